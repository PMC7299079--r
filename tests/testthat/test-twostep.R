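test_that("cluster cost is the size-weighted within-cluster entropy", {
  # identical members on all items -> zero cost
  counts <- matrix(c(5, 0, 0, 0, 5, 0), 2, 3, byrow = TRUE)
  expect_equal(cluster_cost(counts, 5), 0)
  # single item, 2 members split across 2 levels -> 2 * ln 2
  expect_equal(cluster_cost(matrix(c(1, 1, 0), 1), 2), 2 * log(2))
  expect_error(cluster_cost(matrix(0, 1, 3), 0), "empty")
  # random tables agree with the loop-based oracle
  set.seed(11)
  for (i in 1:50) {
    X <- matrix(sample.int(3L, 8 * 3, replace = TRUE), 8, 3)
    counts <- t(sapply(1:3, function(j) tabulate(X[, j], 3)))
    expect_equal(cluster_cost(counts, 8), oracle_xi(X), tolerance = 1e-12)
  }
})

test_that("merge distance is non-negative and zero for identical compositions", {
  set.seed(12)
  for (i in 1:100) {
    A <- matrix(sample.int(3L, 6 * 2, replace = TRUE), 6, 2)
    B <- matrix(sample.int(3L, 4 * 2, replace = TRUE), 4, 2)
    d <- oracle_xi(rbind(A, B)) - oracle_xi(A) - oracle_xi(B)
    expect_gte(d, -1e-10)
  }
  # equal-size clusters with identical level composition merge at cost 0
  A <- rbind(c(1L, 2L), c(3L, 1L))
  d <- oracle_xi(rbind(A, A)) - 2 * oracle_xi(A)
  expect_equal(d, 0)
})

test_that("exact-mode pre-clustering yields one pre-cluster per pattern", {
  X <- rbind(c(1L, 2L), c(1L, 2L), c(2L, 2L), c(3L, 1L), c(3L, 1L), c(3L, 1L))
  pc <- precluster(make_profiles(X), threshold = 0)
  expect_length(pc, 3)
  expect_equal(sort(vapply(pc, `[[`, numeric(1), "size")), c(1, 2, 3))
  # five subjects with five distinct patterns found five singletons
  X2 <- cbind(c(1L, 2L, 3L, 1L, 2L), c(1L, 2L, 3L, 2L, 1L))
  pc2 <- precluster(make_profiles(X2), threshold = 0)
  expect_length(pc2, 5)
  expect_true(all(vapply(pc2, `[[`, numeric(1), "size") == 1))
})

test_that("infinite threshold collapses everything into one pre-cluster", {
  prof <- random_profiles(30, 3, seed = 21)
  pc <- precluster(prof, threshold = Inf, order_seed = 1)
  expect_length(pc, 1)
  expect_equal(pc[[1]]$size, 30)
})

test_that("incomplete subjects are dropped listwise before clustering", {
  X <- rbind(c(1L, 2L), c(NA, 2L), c(3L, 3L))
  expect_message(pc <- precluster(make_profiles(X)), "incomplete")
  expect_equal(sum(vapply(pc, `[[`, numeric(1), "size")), 2)
})

test_that("two well-separated blocks are recovered exactly at k = 2", {
  X <- rbind(matrix(1L, 20, 3), matrix(3L, 20, 3))
  fit <- twostep_fit(make_profiles(X), k_max = 2)
  a <- cluster_assignment(fit, 2)
  expect_equal(unname(a[sprintf("S%03d", 1:20)]), rep(a[["S001"]], 20))
  expect_equal(unname(a[sprintf("S%03d", 21:40)]), rep(a[["S021"]], 20))
  expect_false(a[["S001"]] == a[["S021"]])
  # k = 1 partition is constant
  expect_equal(unname(cluster_assignment(twostep_fit(make_profiles(X),
                                                     k_max = 1), 1)),
               rep(1L, 40))
})

test_that("agglomeration agrees with exhaustive set-partition search", {
  # separated instances where the greedy path attains the global optimum
  for (seed in 1:4) {
    set.seed(seed)
    centers <- matrix(sample.int(3L, 2 * 4, replace = TRUE), 2, 4)
    while (all(centers[1, ] == centers[2, ]))
      centers[2, ] <- sample.int(3L, 4, replace = TRUE)
    X <- centers[rep(1:2, each = 3), ]
    # add one noisy row per block
    X <- rbind(X, centers)
    X[nrow(X), 1] <- (X[nrow(X), 1] %% 3L) + 1L
    prof <- make_profiles(X)
    pc <- precluster(prof, threshold = 0)
    npc <- length(pc)
    expect_lte(npc, 8)
    agg <- agglomerate(pc, k_min = 1)
    for (k in 1:min(3, npc)) {
      got_cost <- agg$xi_totals[[as.character(k)]]
      Xcc <- cogclust:::profile_matrix(prof)
      # oracle works on subject rows grouped by the greedy assignment
      assign <- agg$partitions[[as.character(k)]]
      direct <- sum(sapply(unique(assign), function(g) {
        oracle_xi(Xcc[names(assign)[assign == g], , drop = FALSE])
      }))
      expect_equal(got_cost, direct, tolerance = 1e-9)
      best <- oracle_best_partition(Xcc, k)
      expect_equal(got_cost, best$cost, tolerance = 1e-9)
    }
  }
})

test_that("subject order does not affect the exact-mode partition", {
  prof <- generate_sample(two_class_preset(), N = 120, seed = 31)$profiles
  fit1 <- twostep_fit(prof, k_max = 2)
  perm <- sample(nrow(prof))
  fit2 <- twostep_fit(prof[perm, ], k_max = 2)
  a1 <- cluster_assignment(fit1, 2)
  a2 <- cluster_assignment(fit2, 2)
  expect_equal(a1[sort(names(a1))], a2[sort(names(a2))])
})

test_that("fit indices follow the entropy-cost + penalty form", {
  prof <- generate_sample(two_class_preset(), N = 150, seed = 32)$profiles
  fit <- twostep_fit(prof, k_max = 3)
  m <- 10 * 2   # per-cluster free parameters for 10 three-level items
  for (i in seq_len(nrow(fit$indices))) {
    k <- fit$indices$k[i]
    cost <- fit$indices$cost[i]
    expect_equal(fit$indices$AIC[i], 2 * cost + 2 * k * m)
    expect_equal(fit$indices$BIC[i], 2 * cost + k * m * log(fit$n))
  }
  # entropy analog: 1 at k = 1, inside [0, 1] beyond
  expect_equal(fit$indices$entropy[1], 1)
  expect_true(all(fit$indices$entropy >= 0 & fit$indices$entropy <= 1))
  # cost at k = 1 equals the saturated one-class multinomial deviance part
  X <- cogclust:::profile_matrix(prof)
  expect_equal(fit$indices$cost[1], oracle_xi(X), tolerance = 1e-9)
})

test_that("k_max beyond the number of pre-clusters truncates with a warning", {
  X <- rbind(matrix(1L, 5, 2), matrix(3L, 5, 2))
  expect_warning(fit <- twostep_fit(make_profiles(X), k_max = 4),
                 "truncated")
  expect_equal(max(fit$indices$k), 2)
  expect_true(fit$truncated)
})

test_that("continuous two-step separates well-spaced gaussian blocks", {
  set.seed(41)
  z <- data.frame(subject_id = sprintf("S%03d", 1:60),
                  a = c(rnorm(30, -2, .3), rnorm(30, 2, .3)),
                  b = c(rnorm(30, 2, .3), rnorm(30, -2, .3)))
  fit <- twostep_fit_z(z, k_max = 4)
  a <- cluster_assignment(fit, 2)
  expect_equal(length(unique(a[sprintf("S%03d", 1:30)])), 1)
  expect_equal(length(unique(a[sprintf("S%03d", 31:60)])), 1)
  sel <- select_best(index_path(fit$indices[, c("k", "AIC", "BIC")] |>
    transform(entropy = c(1, rep(0.5, nrow(fit$indices) - 1)))))
  expect_equal(sel$chosen_k, 2)
})
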