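test_that("crosstab counts match a hand tally", {
  a <- setNames(c(1, 1, 1, 2, 2, 2), sprintf("s%d", 1:6))
  f <- setNames(c("below", "below", "within", "above", "above", "within"),
                sprintf("s%d", 1:6))
  tab <- crosstab(a, f)
  expect_equal(tab["1", "below"], 2L)
  expect_equal(tab["1", "within"], 1L)
  expect_equal(tab["2", "above"], 2L)
  expect_equal(sum(tab), 6L)
  expect_equal(attr(tab, "row_pct")["1", "below"], 100 * 2 / 3)
  # single cluster -> single-row table
  tab1 <- crosstab(setNames(rep(1, 6), names(a)), f)
  expect_equal(nrow(tab1), 1L)
  expect_error(crosstab(a, setNames("below", "zzz")), "no shared subjects")
})

test_that("Pearson statistic matches the explicit expected-count oracle", {
  set.seed(8)
  for (i in 1:60) {
    tab <- matrix(rpois(6, 40) + 1L, 2, 3)
    res <- chi_square(tab)
    expect_equal(res$statistic, oracle_chisq(tab), tolerance = 1e-9)
    expect_equal(res$df, 2)
    expect_equal(res$p_value, pchisq(res$statistic, 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # proportional rows -> statistic 0
  expect_equal(chi_square(rbind(c(10, 20, 30), c(20, 40, 60)))$statistic, 0)
  expect_error(chi_square(rbind(c(0, 0, 0), c(1, 2, 3))), "zero margin")
  expect_error(chi_square(matrix(1:3, 1)), "2 x 2")
})

test_that("published composition tables reproduce their printed statistics", {
  fix <- published_counts()
  expect_equal(nrow(fix), 20L)
  for (i in seq_len(nrow(fix))) {
    tab <- rbind(as.numeric(fix[i, 3:5]), as.numeric(fix[i, 6:8]))
    stat <- chi_square(tab)$statistic
    printed <- fix$chi_sq_published[i]
    dp <- nchar(sub("^[^.]*\\.?", "", as.character(printed)))
    expect_equal(round(stat, dp), printed,
                 info = paste(fix$method[i], fix$test[i]))
  }
})

test_that("Low/High labelling follows the below-norm share", {
  X <- rbind(matrix(1L, 6, 2),              # all below
             matrix(c(2L, 3L), 6, 2, byrow = TRUE))
  prof <- make_profiles(X)
  a <- setNames(rep(c(1L, 2L), each = 6), prof$subject_id)
  lab <- label_profiles(a, prof)
  expect_equal(unname(lab["1"]), "Low")
  expect_equal(unname(lab["2"]), "High")
  # identical compositions tie and are flagged
  prof2 <- make_profiles(rbind(matrix(1L, 3, 2), matrix(1L, 3, 2)))
  a3 <- setNames(rep(c(1L, 2L), each = 3), prof2$subject_id)
  expect_warning(lab3 <- label_profiles(a3, prof2), "identical")
  expect_true(attr(lab3, "tie"))
  expect_error(
    label_profiles(setNames(rep(1, nrow(prof)), prof$subject_id), prof),
    "exactly 2")
})

test_that("the published two-step composition labels cluster 1 as Low", {
  fix <- published_counts()
  ts <- fix[fix$method == "twostep", ]
  # rebuild a subject-level fixture consistent with the count table
  rows <- list()
  for (cl in 1:2) {
    cols <- if (cl == 1) 3:5 else 6:8
    n_cl <- sum(ts[1, cols])
    X <- matrix(NA_integer_, n_cl, nrow(ts))
    for (j in seq_len(nrow(ts))) {
      X[, j] <- rep(1:3, times = as.numeric(ts[j, cols]))
    }
    rows[[cl]] <- X
  }
  X <- rbind(rows[[1]], rows[[2]])
  prof <- make_profiles(X, items = ts$test)
  a <- setNames(rep(c(1L, 2L), c(nrow(rows[[1]]), nrow(rows[[2]]))),
                prof$subject_id)
  lab <- label_profiles(a, prof)
  expect_equal(unname(lab["1"]), "Low")
  # and crosstab on any item reproduces the fixture counts
  f <- setNames(as.character(prof[[ts$test[1]]]), prof$subject_id)
  tab <- crosstab(a, f)
  expect_equal(unname(tab["1", c("below", "within", "above")]),
               as.integer(ts[1, 3:5]))
})

test_that("label alignment finds the permutation maximizing agreement", {
  a <- setNames(rep(1:3, each = 10), sprintf("s%02d", 1:30))
  b <- setNames(c(3, 1, 2)[a], names(a))   # relabelled copy
  al <- align_labels(a, b)
  expect_equal(as.vector(al), unname(a))
  expect_equal(cohen_kappa(a, al)$kappa, 1)
  # identity kept when the diagonal is already maximal
  a2 <- setNames(rep(1:2, c(50, 50)), sprintf("t%02d", 1:100))
  b2 <- a2
  b2[c(1:10, 51:55)] <- 3 - b2[c(1:10, 51:55)]  # confusion [[40,10],[5,45]]
  al2 <- align_labels(a2, b2)
  expect_equal(as.vector(al2), unname(b2))
  expect_error(align_labels(a, b2[1:30]), "no shared|differing")
})

test_that("random independent labels align to roughly chance agreement", {
  set.seed(19)
  n <- 4000
  a <- setNames(sample(1:2, n, TRUE), sprintf("r%04d", 1:n))
  b <- setNames(sample(1:2, n, TRUE), names(a))
  rep <- cohen_kappa(a, align_labels(a, b))
  expect_lt(abs(rep$percent_agreement - 50), 4)
  expect_lt(abs(rep$kappa), 0.06)
})

test_that("kappa follows its definition and relabelling invariance", {
  # hand-computed 100-subject confusion [[45,5],[10,40]]
  a <- setNames(rep(c(1, 2), c(50, 50)), sprintf("u%03d", 1:100))
  b <- a
  b[46:50] <- 2
  b[51:60] <- 1
  # margins: rows 50/50, columns 55/45 -> p_e = 0.5*0.55 + 0.5*0.45 = 0.5
  rep <- cohen_kappa(a, b)
  expect_equal(rep$p_o, 0.85)
  expect_equal(rep$p_e, 0.5)
  expect_equal(rep$kappa, (0.85 - 0.5) / (1 - 0.5))
  expect_equal(cohen_kappa(a, a)$kappa, 1)
  # chance-level confusion [[25,25],[25,25]]
  a4 <- setNames(rep(c(1, 2), each = 50), sprintf("v%03d", 1:100))
  b4 <- setNames(rep(c(1, 2, 1, 2), each = 25), names(a4))
  expect_equal(cohen_kappa(a4, b4)$kappa, 0)
  # consistent relabelling of both assignments leaves kappa unchanged
  set.seed(23)
  for (i in 1:100) {
    n <- 40
    x <- setNames(sample(1:3, n, TRUE), sprintf("w%02d", 1:n))
    y <- setNames(sample(1:3, n, TRUE), names(x))
    k1 <- cohen_kappa(x, y)$kappa
    perm <- sample(1:3)
    k2 <- cohen_kappa(setNames(perm[x], names(x)),
                      setNames(perm[y], names(y)))$kappa
    expect_equal(k2, k1, tolerance = 1e-12)
  }
})

test_that("kappa agrees with an established implementation", {
  skip_if_not_installed("e1071")
  set.seed(29)
  a <- setNames(sample(1:3, 200, TRUE), sprintf("x%03d", 1:200))
  b <- setNames(ifelse(runif(200) < .7, a, sample(1:3, 200, TRUE)), names(a))
  conf <- table(a, b)
  expect_equal(cohen_kappa(a, b)$kappa,
               e1071::classAgreement(conf)$kappa, tolerance = 1e-12)
})

test_that("within-stratum refits agree with the whole-sample solution", {
  cfg <- strata_preset()
  samp <- generate_sample(cfg, N = 500, seed = 51)
  fit <- lca_path(samp$profiles, k_max = 2, n_starts = 5, seed = 51)
  whole <- cluster_assignment(fit, 2)
  val <- within_stratum_validation(samp$profiles, samp$stratum, whole,
                                   method = "lca", k_max = 2, min_n = 30,
                                   seed = 51, n_starts = 5)
  expect_gte(length(val), 3)
  for (s in names(val)) {
    expect_true(val[[s]]$chosen_k %in% 1:2)
    if (!is.null(val[[s]]$agreement))
      expect_gt(val[[s]]$agreement$kappa, 0.5)
  }
  # a stratum below the minimum size is skipped with a warning
  small <- setNames(rep(c("A", "B"), c(490, 10)), samp$profiles$subject_id)
  expect_warning(
    within_stratum_validation(samp$profiles, small, whole, method = "lca",
                              k_max = 2, min_n = 30, seed = 1, n_starts = 2),
    "skipped")
})
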