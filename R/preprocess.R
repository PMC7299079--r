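#' @keywords internal
PERFORMANCE_LEVELS <- c("below", "within", "above")

#' Read a wide table of raw test scores
#'
#' Expects a CSV with the subject identifier in the first column and one
#' column per test; empty cells are treated as missing.
#'
#' @param path path to a CSV file.
#' @return A data frame with a `subject_id` character column followed by one
#'   numeric column per test.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("score table needs a subject column plus at least one test column")
  names(df)[1L] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("duplicated subject_id in score table")
  for (j in seq(2L, ncol(df))) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Read a normative reference table
#'
#' The reference gives, for every test, the normative mean `mu`, the
#' normative standard deviation `sigma` (strictly positive) and the scoring
#' `direction`: `"higher_is_better"` for accuracy-type scores or
#' `"lower_is_better"` for time/error-type scores whose z sign must be
#' flipped so that larger standardized values always mean better performance.
#'
#' @param path path to a JSON or YAML file holding a list of records with
#'   fields `test_id`, `mu`, `sigma`, `direction`.
#' @return A data frame with columns `test_id`, `mu`, `sigma`, `direction`.
#' @export
read_norms <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  ref <- do.call(rbind, lapply(recs, function(r) {
    data.frame(test_id = as.character(r$test_id), mu = as.numeric(r$mu),
               sigma = as.numeric(r$sigma), direction = as.character(r$direction),
               stringsAsFactors = FALSE)
  }))
  validate_norms(ref)
}

validate_norms <- function(ref) {
  stopifnot(all(c("test_id", "mu", "sigma", "direction") %in% names(ref)))
  if (anyDuplicated(ref$test_id)) stop("duplicated test_id in normative reference")
  if (any(!is.finite(ref$sigma)) || any(ref$sigma <= 0))
    stop("invalid normative reference: sigma must be strictly positive")
  bad <- setdiff(unique(ref$direction), c("higher_is_better", "lower_is_better"))
  if (length(bad))
    stop("invalid normative reference: unknown direction ", paste(bad, collapse = ", "))
  ref
}

#' Standardize raw scores against a normative reference
#'
#' Computes z = (x - mu) / sigma per test and flips the sign for tests with
#' `direction = "lower_is_better"`, so that every returned z score is
#' oriented as larger = better performance. Missing raw scores stay missing.
#'
#' @param raw wide data frame as returned by [read_scores()].
#' @param ref normative reference data frame as returned by [read_norms()].
#' @return A wide data frame of z scores with the same shape as `raw`.
#' @export
standardize <- function(raw, ref) {
  ref <- validate_norms(ref)
  tests <- names(raw)[-1L]
  unknown <- setdiff(tests, ref$test_id)
  if (length(unknown))
    stop("missing normative reference for test(s): ", paste(unknown, collapse = ", "))
  z <- raw
  for (t in tests) {
    r <- ref[ref$test_id == t, ]
    zt <- (raw[[t]] - r$mu) / r$sigma
    if (r$direction == "lower_is_better") zt <- -zt
    z[[t]] <- zt
  }
  z
}

#' Band z scores into three performance levels
#'
#' Applies the conventional normative cutoffs: z < -cutoff is `below`
#' (deficit, under the 10th percentile for the default 1.3), -cutoff <= z <
#' cutoff is `within` (normal range) and z >= cutoff is `above` (superior
#' ability, at or over the 90th percentile). Both boundaries are half-open
#' so that z equal to -1.3 is `within` and z equal to 1.3 is `above`.
#' Missing z scores propagate to missing levels.
#'
#' @param z wide data frame of z scores oriented larger = better.
#' @param cutoff positive banding cutoff on the z scale (default 1.3).
#' @return A wide data frame whose item columns are factors with levels
#'   `below`, `within`, `above`.
#' @export
categorize <- function(z, cutoff = 1.3) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  out <- z
  for (t in names(z)[-1L]) {
    lv <- ifelse(z[[t]] < -cutoff, "below",
                 ifelse(z[[t]] < cutoff, "within", "above"))
    out[[t]] <- factor(lv, levels = PERFORMANCE_LEVELS)
  }
  out
}

#' Write / read a categorical profile table
#'
#' Profiles are stored as CSV with the subject identifier first and one
#' column per item holding the strings `below` / `within` / `above`; empty
#' cells are missing.
#'
#' @param profiles wide data frame of performance levels.
#' @param path destination CSV path.
#' @return `write_profiles` returns `path` invisibly; `read_profiles`
#'   returns the profile data frame with factor item columns.
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles
  for (j in seq(2L, ncol(out))) out[[j]] <- as.character(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"))
  names(df)[1L] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  for (j in seq(2L, ncol(df))) {
    vals <- df[[j]]
    bad <- setdiff(unique(vals[!is.na(vals)]), PERFORMANCE_LEVELS)
    if (length(bad)) stop("invalid level(s) in ", names(df)[j], ": ",
                          paste(bad, collapse = ", "))
    df[[j]] <- factor(vals, levels = PERFORMANCE_LEVELS)
  }
  df
}

# Internal: wide profile data frame -> integer matrix (1 = below, 2 = within,
# 3 = above), rownames = subject ids. NAs preserved.
profile_matrix <- function(profiles) {
  stopifnot(is.data.frame(profiles), ncol(profiles) >= 2L)
  ids <- as.character(profiles[[1L]])
  items <- names(profiles)[-1L]
  X <- matrix(NA_integer_, nrow(profiles), length(items),
              dimnames = list(ids, items))
  for (j in seq_along(items)) {
    col <- profiles[[j + 1L]]
    if (is.factor(col)) {
      if (!identical(levels(col), PERFORMANCE_LEVELS))
        col <- factor(as.character(col), levels = PERFORMANCE_LEVELS)
    } else {
      col <- factor(as.character(col), levels = PERFORMANCE_LEVELS)
    }
    X[, j] <- as.integer(col)
  }
  X
}
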