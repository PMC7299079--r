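# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written as plain, loop-based code that
# shares no internals with the package implementation.

LEVELS3 <- c("below", "within", "above")

# wide profile data frame from an integer matrix (1/2/3, NA allowed)
make_profiles <- function(X, items = paste0("item", seq_len(ncol(X)))) {
  df <- data.frame(subject_id = sprintf("S%03d", seq_len(nrow(X))),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X)))
    df[[items[j]]] <- factor(LEVELS3[X[, j]], levels = LEVELS3)
  df
}

random_profiles <- function(n, j, seed) {
  set.seed(seed)
  make_profiles(matrix(sample.int(3L, n * j, replace = TRUE), n, j))
}

# --- chi-squared oracle: explicit expected counts, no library call --------
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

# --- LCA log-likelihood oracle: plain loops over subjects ------------------
oracle_lca_loglik <- function(X, p, pi_arr) {
  p <- unname(p)
  ll <- 0
  for (i in seq_len(nrow(X))) {
    li <- 0
    for (r in seq_along(p)) {
      term <- p[r]
      for (j in seq_len(ncol(X))) {
        if (!is.na(X[i, j])) term <- term * pi_arr[j, r, X[i, j]]
      }
      li <- li + term
    }
    ll <- ll + log(li)
  }
  ll
}

# brute-force maximization of the LCA likelihood by multi-restart BFGS on
# softmax-transformed parameters; independent of the package's EM
oracle_lca_maxloglik <- function(X, R, n_restarts = 60, seed = 1) {
  set.seed(seed)
  J <- ncol(X)
  K <- 3L
  npar <- (R - 1L) + R * J * (K - 1L)
  unpack <- function(th) {
    if (R > 1L) {
      ep <- exp(c(0, th[seq_len(R - 1L)]))
      p <- ep / sum(ep)
    } else p <- 1
    pi_arr <- array(0, c(J, R, K))
    idx <- R - 1L
    for (j in seq_len(J)) for (r in seq_len(R)) {
      e <- exp(c(0, th[idx + 1:2]))
      idx <- idx + 2L
      pi_arr[j, r, ] <- e / sum(e)
    }
    list(p = p, pi = pi_arr)
  }
  nll <- function(th) {
    par <- unpack(th)
    -oracle_lca_loglik(X, par$p, par$pi)
  }
  best <- Inf
  for (s in seq_len(n_restarts)) {
    th0 <- rnorm(npar, sd = 2)
    fit <- tryCatch(stats::optim(th0, nll, method = "BFGS",
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$value < best) best <- fit$value
  }
  -best
}

# --- set-partition oracle for the agglomerative step -----------------------
# all partitions of n elements via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    pos <- length(prefix) + 1L
    if (pos > n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# entropy cost of one cluster of pattern rows (counts built from scratch)
oracle_xi <- function(rows) {
  n <- nrow(rows)
  xi <- 0
  for (j in seq_len(ncol(rows))) {
    for (k in 1:3) {
      c_ <- sum(rows[, j] == k)
      if (c_ > 0) xi <- xi - c_ * log(c_ / n)
    }
  }
  xi
}

# minimum total cost over all partitions of the rows of X into exactly k sets
oracle_best_partition <- function(X, k) {
  parts <- Filter(function(p) max(p) == k, all_partitions(nrow(X)))
  best <- Inf; best_p <- NULL
  for (p in parts) {
    tot <- 0
    for (g in seq_len(k))
      tot <- tot + oracle_xi(X[p == g, , drop = FALSE])
    if (tot < best - 1e-12) { best <- tot; best_p <- p }
  }
  list(cost = best, partition = best_p)
}

# canonical form of a partition labelling for comparisons
canon_partition <- function(p) {
  match(p, unique(p))
}
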