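#' Entropy cost of a cluster of categorical profiles
#'
#' The within-cluster cost used by the two-step merge distance:
#' `xi_v = N_v * sum_j H_vj`, where `H_vj` is the Shannon entropy of item
#' `j`'s level distribution inside cluster `v` (with `0 * log 0 = 0`). A
#' cluster whose members agree on every item costs 0. The merge distance
#' between clusters s and t is the cost increase
#' `d(s, t) = xi(s union t) - xi_s - xi_t`, which is always non-negative
#' and is 0 exactly when the two clusters have identical compositions.
#'
#' @param counts per-item level-count table: items x levels matrix whose
#'   rows each sum to the cluster size.
#' @param size number of members (>= 1).
#' @return The scalar cost `xi_v`.
#' @export
cluster_cost <- function(counts, size) {
  if (size < 1L) stop("empty cluster has no cost")
  counts <- as.matrix(counts)
  if (any(abs(rowSums(counts) - size) > 1e-9))
    stop("count rows must sum to the cluster size")
  cl <- counts * log(counts)
  cl[counts == 0] <- 0
  -sum(cl) + nrow(counts) * size * log(size)
}

# ---- internal sufficient-statistics representation -------------------------
# A cluster set is a list: sizes (P), CC (P x Jc*K categorical counts),
# S / Q (P x Jn continuous sums / sums of squares), members (list of id
# vectors), var0 (Jn regularizing variances), Jc, Jn.

xi_vec <- function(st, sizes = st$sizes, CC = st$CC, S = st$S, Q = st$Q) {
  xi <- numeric(length(sizes))
  if (st$Jc > 0L) {
    cl <- CC * log(CC)
    cl[CC == 0] <- 0
    xi <- xi - rowSums(cl) + st$Jc * sizes * log(sizes)
  }
  if (st$Jn > 0L) {
    v <- Q / sizes - (S / sizes)^2
    v[v < 0] <- 0
    xi <- xi + sizes * 0.5 * rowSums(log(sweep(v, 2L, st$var0, "+")))
  }
  xi
}

# distance from cluster s to every cluster in rows `idx`
dist_to <- function(st, xi, s, idx) {
  ns <- st$sizes[idx] + st$sizes[s]
  CCu <- if (st$Jc > 0L) sweep(st$CC[idx, , drop = FALSE], 2L, st$CC[s, ], "+") else NULL
  Su <- if (st$Jn > 0L) sweep(st$S[idx, , drop = FALSE], 2L, st$S[s, ], "+") else NULL
  Qu <- if (st$Jn > 0L) sweep(st$Q[idx, , drop = FALSE], 2L, st$Q[s, ], "+") else NULL
  xi_u <- xi_vec(st, sizes = ns, CC = CCu, S = Su, Q = Qu)
  d <- xi_u - xi[idx] - xi[s]
  d[d < 0] <- 0   # guard tiny negative rounding
  d
}

make_stats <- function(X, Z = NULL) {
  # X: integer matrix (complete cases) of categorical levels, or NULL
  # Z: numeric matrix of continuous scores, or NULL; one row per subject
  n <- if (!is.null(X)) nrow(X) else nrow(Z)
  Jc <- if (!is.null(X)) ncol(X) else 0L
  Jn <- if (!is.null(Z)) ncol(Z) else 0L
  K <- length(PERFORMANCE_LEVELS)
  CC <- NULL
  if (Jc > 0L) {
    CC <- matrix(0, n, Jc * K)
    for (j in seq_len(Jc))
      CC[cbind(seq_len(n), (j - 1L) * K + X[, j])] <- 1
  }
  S <- Q <- NULL
  var0 <- numeric(0)
  if (Jn > 0L) {
    S <- Z
    Q <- Z^2
    var0 <- apply(Z, 2L, function(col) {
      v <- stats::var(col) * (length(col) - 1) / length(col)
      max(v, 1e-8)
    })
  }
  ids <- if (!is.null(X)) rownames(X) else rownames(Z)
  list(sizes = rep(1, n), CC = CC, S = S, Q = Q,
       members = as.list(ids), var0 = var0, Jc = Jc, Jn = Jn)
}

merge_rows <- function(st, s, t) {
  st$sizes[s] <- st$sizes[s] + st$sizes[t]
  if (st$Jc > 0L) st$CC[s, ] <- st$CC[s, ] + st$CC[t, ]
  if (st$Jn > 0L) {
    st$S[s, ] <- st$S[s, ] + st$S[t, ]
    st$Q[s, ] <- st$Q[s, ] + st$Q[t, ]
  }
  st$members[[s]] <- c(st$members[[s]], st$members[[t]])
  st
}

subset_stats <- function(st, idx) {
  list(sizes = st$sizes[idx],
       CC = if (st$Jc > 0L) st$CC[idx, , drop = FALSE] else NULL,
       S = if (st$Jn > 0L) st$S[idx, , drop = FALSE] else NULL,
       Q = if (st$Jn > 0L) st$Q[idx, , drop = FALSE] else NULL,
       members = st$members[idx], var0 = st$var0, Jc = st$Jc, Jn = st$Jn)
}

#' Pre-cluster profiles into dense regions
#'
#' Single-pass leader pre-clustering: subjects are visited in a seeded
#' random order and each joins the nearest existing pre-cluster when the
#' merge distance does not exceed `threshold`, otherwise founds a new one.
#' With the default `threshold = 0` (exact mode) the pre-clusters are
#' precisely the distinct response patterns, independent of visiting order.
#' Subjects with any missing item are dropped (listwise) with a message,
#' since count-table distances are undefined under missingness.
#'
#' @param profiles wide profile data frame.
#' @param threshold maximum merge distance for joining a pre-cluster.
#' @param order_seed seed for the visiting order (irrelevant at threshold 0).
#' @return A list of pre-clusters, each with `members` (subject ids),
#'   `counts` (items x levels), and `size`; carries the sufficient-statistics
#'   set as attribute `stats`.
#' @export
precluster <- function(profiles, threshold = 0, order_seed = NULL) {
  X <- profile_matrix(profiles)
  cc <- stats::complete.cases(X)
  if (!all(cc)) {
    message(sum(!cc), " incomplete subject(s) dropped for two-step clustering")
    X <- X[cc, , drop = FALSE]
  }
  if (nrow(X) == 0L) stop("no complete-case subjects")
  st1 <- make_stats(X)

  if (threshold <= 0) {
    key <- apply(X, 1L, paste, collapse = "/")
    groups <- split(seq_len(nrow(X)), key)          # sorted by pattern key
    idx_first <- vapply(groups, `[`, integer(1), 1L)
    st <- subset_stats(st1, idx_first)
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      st$sizes[g] <- length(rows)
      if (st$Jc > 0L) st$CC[g, ] <- st$CC[g, ] * length(rows)
      st$members[[g]] <- rownames(X)[rows]
    }
  } else {
    if (!is.null(order_seed)) set.seed(order_seed)
    ord <- sample.int(nrow(X))
    st <- subset_stats(st1, ord[1L])
    xi <- xi_vec(st)
    for (i in ord[-1L]) {
      cand <- subset_stats(st1, i)
      P <- length(st$sizes)
      d <- vapply(seq_len(P), function(v) {
        u <- list(sizes = st$sizes[v] + 1,
                  CC = if (st$Jc > 0L) rbind(st$CC[v, ] + cand$CC[1L, ]) else NULL,
                  S = NULL, Q = NULL, var0 = st$var0, Jc = st$Jc, Jn = st$Jn)
        xi_vec(st, sizes = u$sizes, CC = u$CC) - xi[v] - 0
      }, numeric(1))
      b <- which.min(d)
      if (d[b] <= threshold) {
        st$sizes[b] <- st$sizes[b] + 1
        if (st$Jc > 0L) st$CC[b, ] <- st$CC[b, ] + cand$CC[1L, ]
        st$members[[b]] <- c(st$members[[b]], rownames(X)[i])
        xi[b] <- xi_vec(subset_stats(st, b))
      } else {
        st$sizes <- c(st$sizes, 1)
        st$CC <- rbind(st$CC, cand$CC)
        st$members <- c(st$members, list(rownames(X)[i]))
        xi <- c(xi, 0)
      }
    }
  }

  K <- length(PERFORMANCE_LEVELS)
  out <- lapply(seq_along(st$sizes), function(v) {
    counts <- matrix(st$CC[v, ], ncol = K, byrow = TRUE,
                     dimnames = list(colnames(X), PERFORMANCE_LEVELS))
    list(members = st$members[[v]], counts = counts, size = st$sizes[v])
  })
  attr(out, "stats") <- st
  attr(out, "items") <- colnames(X)
  out
}

#' Agglomerate pre-clusters under the log-likelihood distance
#'
#' Repeatedly merges the pair of clusters with the smallest cost increase
#' `d(s, t) = xi(s union t) - xi_s - xi_t` and records the partition at
#' every cluster count from the number of pre-clusters down to `k_min`.
#' Ties in `d` are broken deterministically: smallest `xi_s + xi_t`, then
#' the lexicographically smallest pair of minimum member ids.
#'
#' @param preclusters result of [precluster()].
#' @param k_min record partitions down to this cluster count (default 1).
#' @return A list with `partitions` (named list: k -> subject_id -> cluster
#'   label map as a named integer vector), `xi_totals` (named numeric: total
#'   within-cluster cost per k), and `items`.
#' @export
agglomerate <- function(preclusters, k_min = 1L) {
  st <- attr(preclusters, "stats")
  if (is.null(st)) stop("preclusters must come from precluster()")
  P <- length(st$sizes)
  active <- rep(TRUE, P)
  xi <- xi_vec(st)
  minid <- vapply(st$members, function(m) min(m), character(1))

  D <- matrix(Inf, P, P)
  if (P > 1L) {
    for (s in seq_len(P - 1L)) {
      idx <- seq(s + 1L, P)
      D[s, idx] <- dist_to(st, xi, s, idx)
    }
  }

  all_ids <- unlist(st$members, use.names = FALSE)
  partitions <- list()
  xi_totals <- numeric(0)
  assign_partition <- function(k) {
    act <- which(active)
    # canonical labels: decreasing size, tie by smallest member id
    ord <- act[order(-st$sizes[act], minid[act])]
    res <- structure(integer(length(all_ids)), names = all_ids)
    for (i in seq_along(ord)) res[st$members[[ord[i]]]] <- i
    partitions[[as.character(k)]] <<- res
    xi_totals[[as.character(k)]] <<- sum(xi[act])
  }
  assign_partition(P)

  k <- P
  while (k > max(1L, k_min)) {
    # best pair among active clusters (upper triangle)
    sub <- which(active)
    dmin <- Inf; best <- NULL
    for (s in sub) {
      idx <- sub[sub > s]
      if (!length(idx)) next
      ds <- D[s, idx]
      m <- min(ds)
      if (m < dmin - 1e-12) {
        dmin <- m
        cand <- idx[abs(ds - m) <= 1e-12]
        best <- cbind(s, cand)
      } else if (m <= dmin + 1e-12) {
        cand <- idx[abs(ds - m) <= 1e-12]
        best <- rbind(best, cbind(s, cand))
      }
    }
    if (nrow(best) > 1L) {
      sums <- xi[best[, 1L]] + xi[best[, 2L]]
      best <- best[order(sums, minid[best[, 1L]], minid[best[, 2L]]), ,
                   drop = FALSE]
    }
    s <- best[1L, 1L]; t <- best[1L, 2L]
    st <- merge_rows(st, s, t)
    active[t] <- FALSE
    minid[s] <- min(minid[s], minid[t])
    xi[s] <- xi_vec(subset_stats(st, s))
    rest <- which(active & seq_len(P) != s)
    if (length(rest)) {
      d <- dist_to(st, xi, s, rest)
      # store in the upper triangle: element (min, max) of each pair
      D[pmin(rest, s) + P * (pmax(rest, s) - 1L)] <- d
    }
    k <- k - 1L
    assign_partition(k)
  }
  list(partitions = partitions, xi_totals = xi_totals,
       items = attr(preclusters, "items"))
}

#' Two-step clustering of categorical cognitive profiles
#'
#' Composes [precluster()] and [agglomerate()] and computes per-k fit
#' indices: `AIC_k = 2 * sum_v xi_v + 2 * m_k` and
#' `BIC_k = 2 * sum_v xi_v + m_k * log(N)` with `m_k = k * sum_j (K_j - 1)`
#' free parameters, plus an assignment-certainty entropy analog obtained by
#' soft-assigning each subject to the final clusters with weights
#' `exp(-d(i, v))`, where `d(i, v)` is the cost of merging the subject's
#' singleton into cluster v.
#'
#' @param profiles wide profile data frame.
#' @param k_max largest cluster count to report (default 4).
#' @param threshold pre-clustering distance bound (default 0 = exact mode).
#' @param seed seed for the pre-clustering visit order.
#' @return Object of class `cogtwostep`: `solutions` (named list k ->
#'   assignment named integer vector), `indices` (data frame k, cost, AIC,
#'   BIC, entropy), `n`, `items`, `truncated` flag.
#' @examples
#' cfg <- two_class_preset()
#' samp <- generate_sample(cfg, N = 200, seed = 1)
#' ts <- twostep_fit(samp$profiles, k_max = 4)
#' summary(ts)
#' @export
twostep_fit <- function(profiles, k_max = 4L, threshold = 0, seed = NULL) {
  stopifnot(k_max >= 1L)
  pc <- precluster(profiles, threshold = threshold, order_seed = seed)
  st <- attr(pc, "stats")
  P <- length(pc)
  truncated <- k_max > P
  if (truncated)
    warning("k_max = ", k_max, " exceeds the ", P,
            " pre-clusters; path truncated")
  agg <- agglomerate(pc, k_min = 1L)
  ks <- seq_len(min(k_max, P))
  K <- length(PERFORMANCE_LEVELS)
  m_per_k <- st$Jc * (K - 1L) + 2L * st$Jn
  n <- sum(st$sizes)

  solutions <- list()
  indices <- data.frame(k = integer(0), cost = numeric(0), AIC = numeric(0),
                        BIC = numeric(0), entropy = numeric(0))
  for (k in ks) {
    assign <- agg$partitions[[as.character(k)]]
    cost <- agg$xi_totals[[as.character(k)]]
    m_k <- k * m_per_k
    ent <- if (k == 1L) 1 else twostep_entropy(pc, assign, k)
    solutions[[as.character(k)]] <- assign
    indices <- rbind(indices, data.frame(
      k = k, cost = cost, AIC = 2 * cost + 2 * m_k,
      BIC = 2 * cost + m_k * log(n), entropy = ent))
  }
  structure(list(solutions = solutions, indices = indices, n = n,
                 items = agg$items, threshold = threshold,
                 n_preclusters = P, truncated = truncated, seed = seed),
            class = "cogtwostep")
}

# soft assignment certainty: tau_iv proportional to exp(-d(i, v))
twostep_entropy <- function(pc, assign, k) {
  st <- attr(pc, "stats")
  K <- length(PERFORMANCE_LEVELS)
  # rebuild cluster-level stats for the k-partition; all members of a
  # pattern pre-cluster share one profile, so distances are per pattern
  cl_sizes <- tapply(rep(1, length(assign)), assign, sum)
  CCk <- matrix(0, k, st$Jc * K)
  for (v in seq_along(pc)) {
    lab <- assign[[pc[[v]]$members[1L]]]
    CCk[lab, ] <- CCk[lab, ] + as.vector(t(pc[[v]]$counts))
  }
  stk <- list(sizes = as.numeric(cl_sizes[as.character(seq_len(k))]),
              CC = CCk, S = NULL, Q = NULL, var0 = st$var0,
              Jc = st$Jc, Jn = 0L)
  xik <- xi_vec(stk)
  # distances pattern -> cluster (all members of a pattern share them)
  D <- matrix(0, length(pc), k)
  for (v in seq_along(pc)) {
    row <- as.vector(t(pc[[v]]$counts)) / pc[[v]]$size
    un_sizes <- stk$sizes + 1
    CCu <- sweep(CCk, 2L, row, "+")
    D[v, ] <- xi_vec(stk, sizes = un_sizes, CC = CCu) - xik
  }
  D <- D - apply(D, 1L, min)
  tau_pat <- exp(-D)
  tau_pat <- tau_pat / rowSums(tau_pat)
  reps <- vapply(pc, `[[`, numeric(1), "size")
  tau <- tau_pat[rep(seq_along(pc), reps), , drop = FALSE]
  relative_entropy(tau)
}

#' Two-step clustering of continuous standardized scores
#'
#' Variant of [twostep_fit()] for a wide table of z scores instead of
#' banded levels, used to check that a clustering of the underlying
#' continuous battery agrees with the categorical solution. Every complete
#' case starts as its own pre-cluster and the merge cost of a cluster is
#' `xi_v = N_v * sum_j 0.5 * log(s2_j + s2_vj)`, where `s2_vj` is the
#' within-cluster (biased) variance of item j and `s2_j` the whole-sample
#' variance acting as regularizer, so the merge distance stays
#' non-negative. Free parameters per cluster are a mean and a variance per
#' item.
#'
#' @param zscores wide data frame of z scores (subject id first column).
#' @param k_max largest cluster count to report.
#' @return A `cogtwostep` object (without the entropy analog, reported as
#'   `NA` for k > 1).
#' @export
twostep_fit_z <- function(zscores, k_max = 4L) {
  stopifnot(k_max >= 1L)
  Z <- as.matrix(zscores[, -1L, drop = FALSE])
  rownames(Z) <- as.character(zscores[[1L]])
  cc <- stats::complete.cases(Z)
  if (!all(cc)) {
    message(sum(!cc), " incomplete subject(s) dropped for two-step clustering")
    Z <- Z[cc, , drop = FALSE]
  }
  st <- make_stats(NULL, Z)
  pc <- lapply(seq_len(nrow(Z)), function(i)
    list(members = rownames(Z)[i], counts = NULL, size = 1))
  attr(pc, "stats") <- st
  attr(pc, "items") <- colnames(Z)
  P <- length(pc)
  truncated <- k_max > P
  agg <- agglomerate(pc, k_min = 1L)
  n <- nrow(Z)
  m_per_k <- 2L * st$Jn
  solutions <- list()
  indices <- data.frame()
  for (k in seq_len(min(k_max, P))) {
    assign <- agg$partitions[[as.character(k)]]
    cost <- agg$xi_totals[[as.character(k)]]
    m_k <- k * m_per_k
    solutions[[as.character(k)]] <- assign
    indices <- rbind(indices, data.frame(
      k = k, cost = cost, AIC = 2 * cost + 2 * m_k,
      BIC = 2 * cost + m_k * log(n),
      entropy = if (k == 1L) 1 else NA_real_))
  }
  structure(list(solutions = solutions, indices = indices, n = n,
                 items = colnames(Z), threshold = NA_real_,
                 n_preclusters = P, truncated = truncated, seed = NULL),
            class = "cogtwostep")
}

#' @export
print.cogtwostep <- function(x, ...) {
  cat("Two-step clustering:", x$n, "subjects,", length(x$items), "items,",
      x$n_preclusters, "pre-clusters (threshold ", x$threshold, ")\n")
  print(x$indices, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cogtwostep <- function(object, ...) {
  structure(list(fit = object), class = "summary.cogtwostep")
}

#' @export
print.summary.cogtwostep <- function(x, ...) {
  print(x$fit)
  for (k in names(x$fit$solutions)) {
    cat("\nk =", k, "cluster sizes:\n")
    print(table(x$fit$solutions[[k]]))
  }
  invisible(x)
}

#' Extract a flat assignment from a fitted clustering
#'
#' @param x a `cogtwostep` or `coglca_path` object.
#' @param k the cluster count to extract.
#' @return Named integer vector subject_id -> cluster label.
#' @export
cluster_assignment <- function(x, k) {
  if (inherits(x, "cogtwostep")) {
    a <- x$solutions[[as.character(k)]]
    if (is.null(a)) stop("no k = ", k, " solution in this fit")
    return(a)
  }
  if (inherits(x, "coglca_path")) {
    fit <- x$fits[[k]]
    if (is.null(fit)) stop("no k = ", k, " solution in this fit")
    return(stats::setNames(fit$modal_class, rownames(fit$posterior)))
  }
  if (inherits(x, "coglca"))
    return(stats::setNames(x$modal_class, rownames(x$posterior)))
  stop("unsupported object")
}
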