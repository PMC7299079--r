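#' Generator configuration emulating the published two-class structure
#'
#' Builds the synthetic-data configuration for a 10-item executive-function
#' battery with two latent classes (Low / High cognitive profile). The
#' class-conditional level probabilities are the published within-cluster
#' percentages of the latent-class solution (renormalized to sum to one per
#' item and class, since they are printed as rounded percentages) and the
#' prevalences are the published cluster sizes 184/387 and 203/387.
#'
#' @param N default sample size (387, the study cohort size).
#' @return Object of class `cogclust_config`: `N`, `R`, `prevalence`, `pi`
#'   (items x classes x levels array), `items`, `levels`, `strata` (NULL),
#'   `missing_rate`.
#' @export
two_class_preset <- function(N = 387L) {
  items <- c("MCST_categories", "MCST_errors", "CPM47", "AM",
             "ToL_rule_violations", "ToL_correct_moves",
             "ToL_time_violations", "ToL_total_moves",
             "STROOP_time", "STROOP_errors")
  low <- matrix(c(
    38, 36, 26,
    33, 45, 22,
    34, 50, 16,
    49, 31, 20,
    85, 14,  1,
    26, 71,  4,
    75, 24,  1,
    64, 34,  2,
    59, 22, 19,
    36, 32, 33), ncol = 3L, byrow = TRUE)
  high <- matrix(c(
     3, 14, 83,
     4, 30, 66,
     3, 29, 68,
     9, 35, 56,
    37, 56,  7,
     7, 69, 24,
    35, 61,  4,
    22, 63, 15,
    21, 44, 35,
     9, 41, 50), ncol = 3L, byrow = TRUE)
  low <- low / rowSums(low)
  high <- high / rowSums(high)
  pi_arr <- array(0, c(length(items), 2L, 3L),
                  dimnames = list(items, c("Low", "High"), PERFORMANCE_LEVELS))
  pi_arr[, 1L, ] <- low
  pi_arr[, 2L, ] <- high
  structure(list(N = as.integer(N), R = 2L,
                 prevalence = c(Low = 184, High = 203) / 387,
                 pi = pi_arr, items = items, levels = PERFORMANCE_LEVELS,
                 strata = NULL, missing_rate = 0),
            class = "cogclust_config")
}

#' Add the published diagnosis mixing to the two-class preset
#'
#' Extends [two_class_preset()] with four diagnostic strata (BD, DD, PD, SZ)
#' whose class-given-stratum probabilities come from the published
#' latent-class diagnosis distribution: Low/High counts BD 73/61,
#' DD 26/67, PD 19/31, SZ 66/44; stratum sizes are the corresponding
#' totals out of 387.
#'
#' @param N default sample size.
#' @return A `cogclust_config` whose `strata` component holds `names`,
#'   `p_stratum` and `class_given_stratum` (strata x classes matrix).
#' @export
strata_preset <- function(N = 387L) {
  cfg <- two_class_preset(N)
  counts <- rbind(BD = c(73, 61), DD = c(26, 67),
                  PD = c(19, 31), SZ = c(66, 44))
  colnames(counts) <- c("Low", "High")
  cfg$strata <- list(
    names = rownames(counts),
    p_stratum = rowSums(counts) / sum(counts),
    class_given_stratum = counts / rowSums(counts)
  )
  cfg
}

#' Draw a labelled synthetic sample from a generator configuration
#'
#' Samples, for each subject, a latent class from the prevalences (or a
#' stratum and then a class given the stratum when mixing is configured)
#' and then each item level independently from the class-conditional
#' probabilities (local independence). Missing cells, if requested, are
#' knocked out completely at random. Fully reproducible under `seed`.
#'
#' @param config a `cogclust_config`.
#' @param N sample size (defaults to `config$N`).
#' @param seed mandatory integer seed.
#' @param missing_rate overrides `config$missing_rate` when given.
#' @return A list: `profiles` (wide data frame of factor levels),
#'   `true_class` (named integer vector), `stratum` (named factor or NULL).
#' @export
generate_sample <- function(config, N = config$N, seed,
                            missing_rate = config$missing_rate) {
  stopifnot(inherits(config, "cogclust_config"), N >= 1L)
  if (missing(seed)) stop("a seed is required for reproducible generation")
  set.seed(seed)
  R <- config$R
  J <- length(config$items)
  ids <- sprintf("S%04d", seq_len(N))

  stratum <- NULL
  if (!is.null(config$strata)) {
    st <- config$strata
    stratum <- factor(sample(st$names, N, replace = TRUE, prob = st$p_stratum),
                      levels = st$names)
    cls <- vapply(as.integer(stratum), function(s)
      sample.int(R, 1L, prob = st$class_given_stratum[s, ]), integer(1))
    names(stratum) <- ids
  } else {
    cls <- sample.int(R, N, replace = TRUE, prob = config$prevalence)
  }
  names(cls) <- ids

  X <- matrix(NA_integer_, N, J, dimnames = list(ids, config$items))
  for (r in seq_len(R)) {
    idx <- which(cls == r)
    if (!length(idx)) next
    for (j in seq_len(J)) {
      X[idx, j] <- sample.int(3L, length(idx), replace = TRUE,
                              prob = config$pi[j, r, ])
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(N * J) < missing_rate, N, J)
    X[drop] <- NA_integer_
  }
  profiles <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (j in seq_len(J)) {
    profiles[[config$items[j]]] <- factor(PERFORMANCE_LEVELS[X[, j]],
                                          levels = PERFORMANCE_LEVELS)
  }
  list(profiles = profiles, true_class = cls, stratum = stratum)
}

#' Default synthetic normative reference for a set of tests
#'
#' Convenience reference for exercising the preprocessing layer end to end:
#' every test gets mu = 50, sigma = 10; the time/error-type tests are marked
#' `lower_is_better` so the direction flip is exercised.
#'
#' @param items test identifiers.
#' @return A normative-reference data frame.
#' @export
synthetic_norms <- function(items) {
  lower <- grepl("errors|violations|time|moves", items, ignore.case = TRUE)
  data.frame(test_id = items, mu = 50, sigma = 10,
             direction = ifelse(lower, "lower_is_better", "higher_is_better"),
             stringsAsFactors = FALSE)
}

#' Emit raw scores consistent with a sample's performance levels
#'
#' For every observed level a z score is drawn uniformly within the level's
#' band (below: \[-3, -1.3), within: \[-1.3, 1.3), above: \[1.3, 3\]) and
#' the standardization is inverted to raw units, flipping the sign for
#' `lower_is_better` tests. By construction,
#' `categorize(standardize(raw, ref))` reproduces the sample's levels.
#'
#' @param sample a list with a `profiles` element as from
#'   [generate_sample()].
#' @param ref normative reference covering the sample's items.
#' @param seed integer seed.
#' @return A wide raw-score data frame.
#' @export
emit_raw_scores <- function(sample, ref, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  ref <- validate_norms(ref)
  profiles <- sample$profiles
  X <- profile_matrix(profiles)
  raw <- data.frame(subject_id = rownames(X), stringsAsFactors = FALSE)
  lo <- c(-3, -1.3, 1.3)
  hi <- c(-1.3, 1.3, 3)
  for (j in seq_len(ncol(X))) {
    t <- colnames(X)[j]
    r <- ref[ref$test_id == t, ]
    if (nrow(r) != 1L) stop("missing normative reference for ", t)
    lev <- X[, j]
    z <- rep(NA_real_, nrow(X))
    o <- which(!is.na(lev))
    z[o] <- stats::runif(length(o), lo[lev[o]], hi[lev[o]])
    x <- if (r$direction == "lower_is_better") r$mu - z * r$sigma else
      r$mu + z * r$sigma
    raw[[t]] <- x
  }
  raw
}

#' @export
print.cogclust_config <- function(x, ...) {
  cat("Synthetic generator config:", x$R, "classes,", length(x$items),
      "items, default N =", x$N, "\n")
  cat("  prevalences:", paste(sprintf("%s %.3f", names(x$prevalence),
                                      x$prevalence), collapse = ", "), "\n")
  if (!is.null(x$strata))
    cat("  strata:", paste(x$strata$names, collapse = ", "), "\n")
  if (x$missing_rate > 0) cat("  missing rate:", x$missing_rate, "\n")
  invisible(x)
}
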