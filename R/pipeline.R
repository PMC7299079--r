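#' Run the full clustering pipeline
#'
#' End-to-end orchestration: optional normative preprocessing of raw
#' scores, per-method fitting over k = 1..k_max, selection of k by the
#' consecutive-change rule, per-item contingency tables with chi-squared
#' tests at the chosen k, Low/High profile labelling (when k = 2),
#' cross-method agreement (when both methods run), and within-stratum
#' validation when strata are supplied. All artifacts are returned and,
#' when `out_dir` is given, written as JSON/TSV so stages are diffable and
#' reloadable. All randomness flows from `seed`.
#'
#' @param profiles wide profile data frame, or `NULL` when `raw` + `norms`
#'   are given.
#' @param raw optional wide raw-score data frame (or CSV path) to
#'   standardize and band first.
#' @param norms optional normative reference (data frame or JSON/YAML path).
#' @param methods subset of `c("lca", "twostep")`.
#' @param k_max largest cluster count considered (>= 2).
#' @param seed integer seed for every stochastic step.
#' @param n_starts EM restarts for the latent-class fits.
#' @param threshold two-step pre-clustering distance bound.
#' @param strata optional named vector subject_id -> stratum label.
#' @param out_dir optional output directory for report files.
#' @return Object of class `cogclust_report`: per-method `fits`, `paths`,
#'   `selections`, `assignments` (at the chosen k), `chi_square` tables,
#'   `profile_labels`, `cross_method` agreement, `strata_validation`,
#'   plus the run `config`.
#' @examples
#' samp <- generate_sample(two_class_preset(), N = 150, seed = 7)
#' rep <- run_pipeline(samp$profiles, methods = "lca", k_max = 3,
#'                     seed = 7, n_starts = 5)
#' rep$selections$lca$chosen_k
#' @export
run_pipeline <- function(profiles = NULL, raw = NULL, norms = NULL,
                         methods = c("lca", "twostep"), k_max = 4L,
                         seed = 1L, n_starts = 20L, threshold = 0,
                         strata = NULL, out_dir = NULL) {
  methods <- match.arg(methods, c("lca", "twostep"), several.ok = TRUE)
  if (k_max < 2L) stop("config validation: k_max must be at least 2")
  if (is.null(profiles)) {
    if (is.null(raw) || is.null(norms))
      stop("config validation: provide either profiles or raw + norms")
    if (is.character(raw)) raw <- read_scores(raw)
    if (is.character(norms)) norms <- read_norms(norms)
    profiles <- categorize(standardize(raw, norms))
  }

  fits <- list(); paths <- list(); selections <- list(); assignments <- list()
  chis <- list(); labels <- list()
  for (m in methods) {
    fit <- if (m == "lca") {
      lca_path(profiles, k_max = k_max, n_starts = n_starts, seed = seed)
    } else {
      twostep_fit(profiles, k_max = k_max, threshold = threshold, seed = seed)
    }
    path <- index_path(fit)
    sel <- select_best(path)
    k <- max(sel$chosen_k, 1L)
    assignment <- cluster_assignment(fit, k)
    fits[[m]] <- fit
    paths[[m]] <- path
    selections[[m]] <- sel
    assignments[[m]] <- assignment
    if (k >= 2L) {
      chis[[m]] <- item_chi_squares(assignment, profiles)
      if (k == 2L)
        labels[[m]] <- label_profiles(assignment, profiles)
    }
  }

  cross <- NULL
  if (length(methods) == 2L) {
    a <- assignments[[methods[1L]]]
    b <- assignments[[methods[2L]]]
    if (length(unique(a)) == length(unique(b)) && length(unique(a)) >= 2L) {
      shared <- intersect(names(a), names(b))
      aligned <- align_labels(a[shared], b[shared])
      cross <- cohen_kappa(a[shared], aligned)
    }
  }

  strata_val <- NULL
  if (!is.null(strata)) {
    strata_val <- lapply(stats::setNames(methods, methods), function(m)
      within_stratum_validation(profiles, strata, assignments[[m]],
                                method = m, k_max = k_max, seed = seed,
                                n_starts = n_starts, threshold = threshold))
  }

  report <- structure(list(
    fits = fits, paths = paths, selections = selections,
    assignments = assignments, chi_square = chis, profile_labels = labels,
    cross_method = cross, strata_validation = strata_val,
    config = list(methods = methods, k_max = k_max, seed = seed,
                  n_starts = n_starts, threshold = threshold,
                  package_version = as.character(utils::packageVersion("cogclust")))
  ), class = "cogclust_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# per-item 2..k x 3 contingency tables + chi-squared at the chosen k
item_chi_squares <- function(assignment, profiles) {
  items <- names(profiles)[-1L]
  ids <- as.character(profiles[[1L]])
  out <- lapply(items, function(it) {
    f <- stats::setNames(profiles[[it]], ids)   # factor keeps level order
    tab <- crosstab(assignment, f)
    res <- tryCatch(chi_square(tab), error = function(e) NULL)
    list(table = tab, chi_square = res)
  })
  stats::setNames(out, items)
}

#' Write a pipeline report bundle to disk
#'
#' Emits, per method: the fit-index path and selection as JSON, the chosen
#' assignment as TSV (`subject_id`, `cluster`), chi-squared summaries as
#' TSV; plus a cross-method agreement JSON when available and a
#' `fit_changes.tsv` summarizing the consecutive index changes for both
#' methods (the index-change comparison view).
#'
#' @param report a `cogclust_report`.
#' @param out_dir destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  changes_all <- NULL
  for (m in names(report$paths)) {
    path <- report$paths[[m]]
    sel <- report$selections[[m]]
    jsonlite::write_json(list(
      method = m, indices = path$indices, changes = path$changes,
      chosen_k = sel$chosen_k, winners = as.list(sel$winners),
      rationale = sel$rationale, config = report$config
    ), file.path(out_dir, paste0(m, "_selection.json")),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")

    a <- report$assignments[[m]]
    utils::write.table(
      data.frame(subject_id = names(a), cluster = unname(a)),
      file.path(out_dir, paste0(m, "_assignment.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)

    if (!is.null(report$chi_square[[m]])) {
      tab <- do.call(rbind, lapply(names(report$chi_square[[m]]), function(it) {
        cs <- report$chi_square[[m]][[it]]$chi_square
        data.frame(item = it,
                   statistic = if (is.null(cs)) NA_real_ else cs$statistic,
                   df = if (is.null(cs)) NA_integer_ else cs$df,
                   p_value = if (is.null(cs)) NA_real_ else cs$p_value)
      }))
      utils::write.table(tab, file.path(out_dir, paste0(m, "_chi_square.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ch <- path$changes
    ch$method <- m
    changes_all <- rbind(changes_all, ch)
  }
  if (!is.null(changes_all))
    utils::write.table(changes_all, file.path(out_dir, "fit_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$cross_method)) {
    x <- report$cross_method
    jsonlite::write_json(list(
      kappa = x$kappa, p_o = x$p_o, p_e = x$p_e,
      percent_agreement = x$percent_agreement, n = x$n,
      confusion = as.data.frame.matrix(x$confusion)
    ), file.path(out_dir, "cross_method_agreement.json"),
    auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' @export
print.cogclust_report <- function(x, ...) {
  cat("cogclust pipeline report (seed ", x$config$seed, ")\n", sep = "")
  for (m in names(x$selections)) {
    cat("\n[", m, "] ", x$selections[[m]]$rationale, "\n", sep = "")
    if (!is.null(x$profile_labels[[m]])) {
      lab <- x$profile_labels[[m]]
      shares <- attr(lab, "below_share")
      cat("  profile labels:",
          paste(sprintf("cluster %s = %s (below share %.2f)",
                        names(lab), lab, shares), collapse = "; "), "\n")
    }
  }
  if (!is.null(x$cross_method))
    cat(sprintf("\nCross-method agreement: kappa %.3f (%.1f%%)\n",
                x$cross_method$kappa, x$cross_method$percent_agreement))
  invisible(x)
}
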