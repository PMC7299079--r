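#' Cross-tabulate a cluster assignment against levels or strata
#'
#' @param assignment named vector subject_id -> cluster label.
#' @param f named vector subject_id -> level or stratum (character/factor).
#' @return An integer matrix clusters x categories with a `row_pct`
#'   attribute holding the per-row percentages.
#' @export
crosstab <- function(assignment, f) {
  ids <- intersect(names(assignment), names(f))
  if (length(ids) == 0L) stop("no shared subjects between assignment and factor")
  a <- assignment[ids]
  b <- f[ids]
  b <- b[!is.na(b)]
  a <- a[names(b)]
  tab <- table(cluster = a, category = b)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  attr(m, "row_pct") <- 100 * m / rowSums(m)
  m
}

#' Pearson chi-squared test on a contingency table
#'
#' Plain Pearson statistic with expected counts from the independence
#' margins and no continuity correction, as used to compare level
#' frequencies between clusters.
#'
#' @param tab integer matrix of counts, at least 2 x 2.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("undefined expected counts: zero margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Label a two-cluster solution as Low / High cognitive profile
#'
#' The cluster with the larger overall share of `below`-norm performances
#' across all items is the Low Cognitive Profile; the other is High. An
#' exact tie is flagged and resolved by cluster label order.
#'
#' @param assignment named vector subject_id -> cluster label (k = 2).
#' @param profiles wide profile data frame.
#' @return Named character vector cluster label -> "Low"/"High", with
#'   attributes `below_share` and `tie`.
#' @export
label_profiles <- function(assignment, profiles) {
  labs <- sort(unique(assignment))
  if (length(labs) != 2L) stop("Low/High labelling requires exactly 2 clusters")
  X <- profile_matrix(profiles)
  ids <- intersect(names(assignment), rownames(X))
  share <- vapply(labs, function(l) {
    sub <- X[ids[assignment[ids] == l], , drop = FALSE]
    mean(sub == 1L, na.rm = TRUE)     # level 1 = below
  }, numeric(1))
  tie <- isTRUE(all.equal(share[1L], share[2L]))
  if (tie) warning("clusters have identical below-norm shares; ",
                   "Low assigned to the first cluster label")
  low <- if (tie) labs[1L] else labs[which.max(share)]
  out <- stats::setNames(ifelse(labs == low, "Low", "High"), labs)
  attr(out, "below_share") <- stats::setNames(share, labs)
  attr(out, "tie") <- tie
  out
}

#' Align the labels of one clustering to another
#'
#' Exhaustively searches the k! label permutations of `assignB` for the one
#' maximizing the diagonal of the confusion matrix with `assignA`, so that
#' chance-corrected agreement can be computed between independently fitted
#' clusterings.
#'
#' @param assignA,assignB named vectors over the same subjects with the
#'   same number of clusters (k <= 6).
#' @return `assignB` relabelled; the permutation used is attached as
#'   attribute `perm` (new label of old cluster i at position i).
#' @export
align_labels <- function(assignA, assignB) {
  ids <- intersect(names(assignA), names(assignB))
  if (!length(ids)) stop("no shared subjects")
  a <- assignA[ids]; b <- assignB[ids]
  ka <- sort(unique(a)); kb <- sort(unique(b))
  if (length(ka) != length(kb)) stop("differing numbers of clusters")
  k <- length(ka)
  if (k > 6L) stop("exhaustive alignment limited to k <= 6")
  conf <- table(factor(a, ka), factor(b, kb))
  perms <- all_perms(k)
  scores <- vapply(seq_len(nrow(perms)), function(i)
    sum(diag(conf[, perms[i, ], drop = FALSE])), numeric(1))
  best <- perms[which.max(scores), ]
  # old label kb[best[j]] becomes new label ka[j]
  map <- stats::setNames(ka, kb[best])
  out <- map[as.character(assignB)]
  names(out) <- names(assignB)
  attr(out, "perm") <- map
  out
}

all_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Cohen's kappa agreement between two aligned clusterings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o` (diagonal share of the confusion matrix) and
#' chance agreement `p_e` from the marginal products. Call
#' [align_labels()] first when the labelings come from independent fits.
#'
#' @param assignA,assignB named vectors over the same subjects.
#' @return Object of class `agreement_report`: `confusion`, `kappa`, `p_o`,
#'   `p_e`, `percent_agreement`, `n`.
#' @export
cohen_kappa <- function(assignA, assignB) {
  ids <- intersect(names(assignA), names(assignB))
  if (!length(ids)) stop("no shared subjects")
  a <- as.character(assignA[ids]); b <- as.character(assignB[ids])
  labs <- sort(unique(c(a, b)))
  conf <- table(factor(a, labs), factor(b, labs))
  n <- sum(conf)
  p_o <- sum(diag(conf)) / n
  p_e <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (isTRUE(all.equal(p_e, 1))) {
    warning("degenerate agreement: chance agreement is 1, kappa undefined")
    NA_real_
  } else (p_o - p_e) / (1 - p_e)
  structure(list(confusion = unclass(conf), kappa = kappa, p_o = p_o,
                 p_e = p_e, percent_agreement = 100 * p_o, n = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement over", x$n, "subjects:\n")
  print(x$confusion)
  cat(sprintf("  observed %.3f, chance %.3f, kappa %.3f (%.1f%% agreement)\n",
              x$p_o, x$p_e, x$kappa, x$percent_agreement))
  invisible(x)
}

#' Internal validity: refit within each stratum and compare
#'
#' Re-runs the chosen clustering method inside every stratum (e.g.
#' diagnosis), reports the stratum-level choice of k, and measures the
#' agreement (Cohen's kappa and percent identically classified, after label
#' alignment) between the whole-sample assignment restricted to the stratum
#' and a stratum-level solution at the whole-sample k.
#'
#' @param profiles wide profile data frame.
#' @param strata named vector subject_id -> stratum label.
#' @param whole_assignment named vector subject_id -> whole-sample cluster.
#' @param method `"lca"` or `"twostep"`.
#' @param k_max largest k for the stratum-level fit path.
#' @param min_n strata smaller than this are skipped with a warning.
#' @param seed seed forwarded to the stratum fits.
#' @param n_starts EM restarts for the latent-class stratum fits.
#' @param threshold pre-clustering bound for the two-step stratum fits.
#' @return A list per stratum with `n`, `chosen_k`, `selection`,
#'   `agreement` (an `agreement_report`, or `NULL` when degenerate).
#' @export
within_stratum_validation <- function(profiles, strata, whole_assignment,
                                      method = c("lca", "twostep"),
                                      k_max = 4L, min_n = 20L, seed = NULL,
                                      n_starts = 20L, threshold = 0) {
  method <- match.arg(method)
  ids <- as.character(profiles[[1L]])
  strata <- strata[ids]
  k_whole <- length(unique(whole_assignment))
  out <- list()
  for (s in sort(unique(strata[!is.na(strata)]))) {
    sel_ids <- ids[!is.na(strata) & strata == s]
    if (length(sel_ids) < min_n) {
      warning("stratum ", s, " has ", length(sel_ids),
              " subjects (< ", min_n, "); skipped")
      next
    }
    sub <- profiles[ids %in% sel_ids, , drop = FALSE]
    if (method == "lca") {
      fit <- lca_path(sub, k_max = k_max, seed = seed, n_starts = n_starts)
    } else {
      fit <- suppressWarnings(  # small strata may not support k_max clusters
        twostep_fit(sub, k_max = k_max, seed = seed, threshold = threshold))
    }
    sel <- select_best(index_path(fit))
    whole_s <- whole_assignment[intersect(names(whole_assignment), sel_ids)]
    agreement <- NULL
    strat_assign <- tryCatch(cluster_assignment(fit, k_whole), error = function(e) NULL)
    if (!is.null(strat_assign)) {
      shared <- intersect(names(whole_s), names(strat_assign))
      ka <- length(unique(whole_s[shared]))
      kb <- length(unique(strat_assign[shared]))
      if (ka == kb && ka >= 2L) {
        aligned <- align_labels(whole_s[shared], strat_assign[shared])
        agreement <- cohen_kappa(whole_s[shared], aligned)
      } else {
        warning("stratum ", s, ": degenerate one-class labelling, ",
                "kappa undefined")
      }
    }
    out[[as.character(s)]] <- list(n = length(sel_ids),
                                   chosen_k = sel$chosen_k,
                                   selection = sel, agreement = agreement)
  }
  out
}

#' Published cluster-composition count tables
#'
#' Per-test counts of subjects scoring below / within / above the normative
#' range in the Low and High cognitive profile clusters, for both clustering
#' methods, together with the published Pearson chi-squared statistic of
#' each 2 x 3 table. Shipped as a plain-text fixture and used to spot-check
#' [chi_square()] against the published values.
#'
#' @return A data frame with columns `method`, `test`, `low_below`,
#'   `low_within`, `low_above`, `high_below`, `high_within`, `high_above`,
#'   `chi_sq_published`.
#' @export
published_counts <- function() {
  path <- system.file("extdata", "cluster_composition_counts.tsv",
                      package = "cogclust", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
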