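#' Fit-index path with consecutive changes
#'
#' Collects AIC, BIC and relative entropy for k = 1..k_max and computes,
#' for each pair of adjacent solutions, the improvement from k-1 to k:
#' information criteria improve when they drop, so
#' `delta_AIC(k) = AIC(k-1) - AIC(k)` (same for BIC); entropy improves when
#' it rises, so `delta_entropy(k) = entropy(k) - entropy(k-1)`. With
#' k_max = 4 the changes are labelled `2vs1`, `3vs2`, `4vs3`. Larger change
#' always means greater improvement.
#'
#' @param x a data frame with columns `k`, `AIC`, `BIC`, `entropy` covering
#'   a contiguous k range starting at 1, or a fitted `cogtwostep` /
#'   `coglca_path` object.
#' @param ... unused.
#' @return Object of class `fit_index_path`: `indices` (the per-k table),
#'   `changes` (data frame with `label`, `k`, `AIC`, `BIC`, `entropy`
#'   improvements) and `method`.
#' @export
index_path <- function(x, ...) UseMethod("index_path")

#' @rdname index_path
#' @export
index_path.data.frame <- function(x, method = NA_character_, ...) {
  need <- c("k", "AIC", "BIC", "entropy")
  stopifnot(all(need %in% names(x)))
  x <- x[order(x$k), , drop = FALSE]
  if (!identical(as.integer(x$k), seq_len(nrow(x))))
    stop("gap error: k must run contiguously from 1")
  if (nrow(x) < 2L) stop("need at least k = 1 and k = 2 to compute changes")
  kk <- x$k[-1L]
  changes <- data.frame(
    label = paste0(kk, "vs", kk - 1L),
    k = kk,
    AIC = -diff(x$AIC),
    BIC = -diff(x$BIC),
    entropy = diff(x$entropy)
  )
  structure(list(indices = x[, need], changes = changes, method = method),
            class = "fit_index_path")
}

#' @rdname index_path
#' @export
index_path.cogtwostep <- function(x, ...) {
  index_path(x$indices[, c("k", "AIC", "BIC", "entropy")], method = "twostep")
}

#' @rdname index_path
#' @export
index_path.coglca_path <- function(x, ...) {
  index_path(x$indices[, c("k", "AIC", "BIC", "entropy")], method = "lca")
}

#' Select the number of clusters by strongest consecutive change
#'
#' For each index the winning k is the one with the largest improvement
#' over the previous solution (ties go to the smaller k); an index whose
#' changes are all non-positive votes for k = 1 (no improvement). The
#' chosen k is the majority vote across AIC, BIC and entropy; a full
#' three-way disagreement falls back to the smallest winning k. This
#' prefers the most parsimonious solution with the strongest gain in fit.
#'
#' @param path a `fit_index_path` object.
#' @return Object of class `cluster_selection`: `chosen_k`, `winners`
#'   (named per-index winning k), `votes`, `rationale`, `method`.
#' @export
select_best <- function(path) {
  stopifnot(inherits(path, "fit_index_path"))
  ch <- path$changes
  winners <- vapply(c("AIC", "BIC", "entropy"), function(idx) {
    v <- ch[[idx]]
    if (all(v <= 0)) return(1L)
    as.integer(ch$k[which.max(v)])   # which.max takes the first = smaller k
  }, integer(1))
  improving <- winners[winners > 1L]   # k = 1 means "this index never improves"
  if (length(improving) == 0L) {
    chosen <- 1L
    how <- " (no index improves at any k)"
  } else {
    tab <- sort(table(improving), decreasing = TRUE)
    if (max(tab) >= 2L) {
      chosen <- as.integer(names(tab)[1L])
      how <- " by majority vote"
    } else {
      chosen <- min(improving)
      how <- " (index disagreement, smallest winning k)"
    }
  }
  rationale <- paste0(
    paste(names(winners), "favours k =", winners, collapse = "; "),
    "; chosen k = ", chosen, how)
  votes <- sum(winners == chosen)
  structure(list(chosen_k = chosen, winners = winners, votes = votes,
                 rationale = rationale, method = path$method,
                 changes = ch),
            class = "cluster_selection")
}

#' @export
print.fit_index_path <- function(x, ...) {
  if (!is.na(x$method)) cat("Method:", x$method, "\n")
  cat("Fit indices:\n")
  print(x$indices, row.names = FALSE)
  cat("Consecutive changes (improvement from k-1 to k):\n")
  print(x$changes, row.names = FALSE)
  invisible(x)
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("Chosen number of clusters:", x$chosen_k, "\n")
  cat(" ", x$rationale, "\n")
  invisible(x)
}
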