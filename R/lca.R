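#' Fit a latent-class model to three-level cognitive profiles
#'
#' Fits a finite mixture of independent multinomials (latent class analysis)
#' to a subjects x items table of ordinal performance levels by
#' expectation-maximization. Each latent class `r` has a prevalence `p[r]`
#' and, for every item `j`, a conditional probability `pi[j, r, k]` of
#' responding at level `k`; items are conditionally independent given class
#' (local independence). Subjects with missing items contribute the product
#' of their observed-item probabilities to the likelihood, so incomplete
#' batteries are retained.
#'
#' The EM is restarted `n_starts` times from random posterior-membership
#' matrices and the start with the highest maximized log-likelihood is kept.
#' Within each start the observed-data log-likelihood is non-decreasing
#' across iterations; conditional probabilities are clipped to
#' `[1e-10, 1 - 1e-10]` to keep the log-likelihood finite on separable data.
#'
#' @param profiles wide data frame of performance levels (first column
#'   subject id, remaining columns factors with levels below/within/above).
#' @param R number of latent classes (>= 1).
#' @param n_starts number of random EM restarts.
#' @param seed integer seed controlling the restarts.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per start.
#' @return An object of class `coglca` with components `R`, `p`
#'   (prevalences), `pi` (items x classes x levels array), `loglik`, `q`
#'   (free parameters), `n_used`, `fit` (loglik, AIC, BIC, entropy),
#'   `posterior` (subjects x classes matrix), `modal_class`, `converged`,
#'   and the log-likelihood trace of the winning start.
#' @seealso [posterior()], [relative_entropy()], [lca_path()]
#' @examples
#' cfg <- two_class_preset()
#' samp <- generate_sample(cfg, N = 200, seed = 1)
#' fit <- lca_fit(samp$profiles, R = 2, n_starts = 5, seed = 1)
#' summary(fit)
#' @export
lca_fit <- function(profiles, R, n_starts = 20L, seed = NULL,
                    tol = 1e-8, max_iter = 5000L) {
  stopifnot(R >= 1L, n_starts >= 1L, max_iter >= 1L, tol > 0)
  X <- profile_matrix(profiles)
  keep <- rowSums(!is.na(X)) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with no observed items dropped from the likelihood")
    X <- X[keep, , drop = FALSE]
  }
  N <- nrow(X)
  J <- ncol(X)
  if (N == 0L) stop("no usable subjects")
  for (j in seq_len(J)) {
    if (length(unique(stats::na.omit(X[, j]))) < 2L && R > 1L)
      warning("item ", colnames(X)[j], " has fewer than 2 observed levels")
  }
  n_patterns <- length(unique(apply(X, 1L, paste, collapse = "/")))
  if (R > n_patterns)
    stop("degenerate model: R = ", R, " exceeds the ", n_patterns,
         " distinct observed response patterns")

  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    tau0 <- matrix(stats::runif(N * R), N, R)
    tau0 <- tau0 / rowSums(tau0)
    run <- lca_em(X, R, tau0, tol, max_iter)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged)
    warning("EM did not converge in ", max_iter, " iterations; best iterate returned")

  K <- length(PERFORMANCE_LEVELS)
  q <- (R - 1L) + R * J * (K - 1L)
  ent <- relative_entropy(best$tau)
  fit <- data.frame(
    loglik = best$loglik,
    AIC = -2 * best$loglik + 2 * q,
    BIC = -2 * best$loglik + q * log(N),
    entropy = ent
  )
  dimnames(best$pi) <- list(colnames(X), paste0("class", seq_len(R)),
                            PERFORMANCE_LEVELS)
  rownames(best$tau) <- rownames(X)
  structure(list(
    R = R, p = stats::setNames(best$p, paste0("class", seq_len(R))),
    pi = best$pi, loglik = best$loglik, q = q, n_used = N,
    fit = fit, posterior = best$tau,
    modal_class = apply(best$tau, 1L, which.max),
    converged = best$converged, loglik_trace = best$trace,
    items = colnames(X), levels = PERFORMANCE_LEVELS,
    n_starts = n_starts, seed = seed, tol = tol
  ), class = "coglca")
}

# Single EM run. X: integer matrix with NAs; tau0: N x R start memberships.
lca_em <- function(X, R, tau0, tol, max_iter) {
  N <- nrow(X); J <- ncol(X); K <- length(PERFORMANCE_LEVELS)
  obs <- !is.na(X)
  # one-hot indicators per item; missing rows are all-zero so they add
  # nothing to log-likelihood sums
  Y <- lapply(seq_len(J), function(j) {
    m <- matrix(0, N, K)
    idx <- which(obs[, j])
    m[cbind(idx, X[idx, j])] <- 1
    m
  })
  tau <- tau0
  ll_old <- -Inf
  ll <- -Inf
  converged <- FALSE
  trace <- numeric(0)
  pi_arr <- array(0, c(J, R, K))
  p <- rep(1 / R, R)
  for (it in seq_len(max_iter)) {
    # M-step from current memberships
    p <- colSums(tau) / N
    p <- pmin(pmax(p, 1e-10), 1)
    p <- p / sum(p)
    logA <- matrix(log(p), N, R, byrow = TRUE)
    for (j in seq_len(J)) {
      num <- crossprod(Y[[j]], tau)                       # K x R
      den <- colSums(tau[obs[, j], , drop = FALSE])       # R
      pij <- sweep(num, 2L, pmax(den, 1e-300), "/")
      pij <- pmin(pmax(pij, 1e-10), 1 - 1e-10)
      pij <- sweep(pij, 2L, colSums(pij), "/")
      pi_arr[j, , ] <- t(pij)
      logA <- logA + Y[[j]] %*% log(pij)                  # N x R
    }
    # E-step + observed-data log-likelihood (log-sum-exp)
    mx <- do.call(pmax, as.data.frame(logA))
    tau <- exp(logA - mx)
    rs <- rowSums(tau)
    ll <- sum(mx + log(rs))
    tau <- tau / rs
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(p = p, pi = pi_arr, tau = tau, loglik = ll,
       converged = converged, trace = trace)
}

#' Posterior class membership for profiles under a fitted model
#'
#' Applies Bayes' rule in log space: `tau[i, r]` is proportional to
#' `p[r] * prod_j pi[j, r, level_ij]` over the subject's observed items,
#' normalized per subject.
#'
#' @param model a fitted `coglca` object.
#' @param profiles wide profile data frame whose items match the model's.
#' @return A list with `tau` (subjects x classes matrix) and `modal_class`.
#' @export
posterior <- function(model, profiles) {
  stopifnot(inherits(model, "coglca"))
  X <- profile_matrix(profiles)
  if (!identical(colnames(X), model$items))
    stop("profile items do not match model items")
  N <- nrow(X); R <- model$R; J <- ncol(X)
  logA <- matrix(log(model$p), N, R, byrow = TRUE)
  for (j in seq_len(J)) {
    pij <- pmin(pmax(model$pi[j, , , drop = FALSE], 1e-300), 1)
    lp <- log(matrix(pij, R, length(PERFORMANCE_LEVELS)))   # R x K
    idx <- X[, j]
    add <- matrix(0, N, R)
    o <- which(!is.na(idx))
    if (length(o)) add[o, ] <- t(lp)[idx[o], , drop = FALSE]
    logA <- logA + add
  }
  mx <- do.call(pmax, as.data.frame(logA))
  tau <- exp(logA - mx)
  tau <- tau / rowSums(tau)
  rownames(tau) <- rownames(X)
  list(tau = tau, modal_class = apply(tau, 1L, which.max))
}

#' Relative entropy of a posterior membership matrix
#'
#' One minus the total Shannon entropy of the class memberships normalized
#' by its maximum `N * log(R)`: 1 means perfectly certain assignment, 0
#' means uniform memberships. Defined as 1 for a single class; `0 * log(0)`
#' is treated as 0.
#'
#' @param tau subjects x classes membership matrix, rows summing to 1.
#' @return A number in `[0, 1]`.
#' @export
relative_entropy <- function(tau) {
  tau <- as.matrix(tau)
  R <- ncol(tau)
  if (R == 1L) return(1)
  h <- -tau * log(tau)
  h[!is.finite(h)] <- 0
  1 - sum(h) / (nrow(tau) * log(R))
}

#' Fit latent-class models along a range of class counts
#'
#' Convenience wrapper fitting `lca_fit` for k = 1..k_max so the fit-index
#' path can feed [select_best()]. Each k gets an independent set of random
#' restarts derived from `seed`.
#'
#' @inheritParams lca_fit
#' @param k_max largest number of classes to fit.
#' @return An object of class `coglca_path`: a list of `coglca` fits indexed
#'   by k, with an `indices` data frame (k, loglik, AIC, BIC, entropy).
#' @export
lca_path <- function(profiles, k_max = 4L, n_starts = 20L, seed = NULL,
                     tol = 1e-8, max_iter = 5000L) {
  stopifnot(k_max >= 1L)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    sk <- if (is.null(seed)) NULL else (seed + 1000L * (k - 1L)) %% .Machine$integer.max
    fits[[k]] <- lca_fit(profiles, R = k, n_starts = n_starts, seed = sk,
                         tol = tol, max_iter = max_iter)
  }
  indices <- do.call(rbind, lapply(seq_len(k_max), function(k)
    cbind(data.frame(k = k), fits[[k]]$fit)))
  structure(list(fits = fits, indices = indices, method = "lca"),
            class = "coglca_path")
}

#' Export / import a fitted latent-class model as JSON
#'
#' @param model a `coglca` object.
#' @param path destination (or source) JSON path.
#' @return `lca_export_json` returns `path` invisibly; `lca_import_json`
#'   returns a `coglca` object (without posterior memberships, which are
#'   recomputed on demand with [posterior()]).
#' @export
lca_export_json <- function(model, path) {
  stopifnot(inherits(model, "coglca"))
  pi_map <- lapply(seq_along(model$items), function(j) {
    cls <- lapply(seq_len(model$R), function(r)
      as.list(stats::setNames(model$pi[j, r, ], model$levels)))
    stats::setNames(cls, paste0("class", seq_len(model$R)))
  })
  names(pi_map) <- model$items
  obj <- list(R = model$R, p = unname(model$p), pi = pi_map,
              loglik = model$loglik, q = model$q, n_used = model$n_used,
              seed = model$seed, n_starts = model$n_starts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname lca_export_json
#' @export
lca_import_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  items <- names(obj$pi)
  R <- as.integer(obj$R)
  K <- length(PERFORMANCE_LEVELS)
  pi_arr <- array(0, c(length(items), R, K),
                  dimnames = list(items, paste0("class", seq_len(R)),
                                  PERFORMANCE_LEVELS))
  for (j in seq_along(items)) for (r in seq_len(R))
    pi_arr[j, r, ] <- unlist(obj$pi[[items[j]]][[paste0("class", r)]])[PERFORMANCE_LEVELS]
  structure(list(
    R = R, p = stats::setNames(as.numeric(obj$p), paste0("class", seq_len(R))),
    pi = pi_arr, loglik = obj$loglik, q = obj$q, n_used = obj$n_used,
    fit = NULL, posterior = NULL, modal_class = NULL, converged = NA,
    items = items, levels = PERFORMANCE_LEVELS,
    n_starts = obj$n_starts, seed = obj$seed
  ), class = "coglca")
}

#' @export
print.coglca <- function(x, ...) {
  cat("Latent-class model:", x$R, "class(es),", length(x$items), "items,",
      x$n_used, "subjects\n")
  cat("  logLik:", format(x$loglik), "  q:", x$q, "\n")
  if (!is.null(x$fit))
    cat("  AIC:", format(x$fit$AIC), "  BIC:", format(x$fit$BIC),
        "  entropy:", format(round(x$fit$entropy, 3)), "\n")
  cat("  prevalences:", paste(format(round(x$p, 3)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.coglca <- function(object, ...) {
  structure(list(model = object), class = "summary.coglca")
}

#' @export
print.summary.coglca <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nConditional response probabilities:\n")
  for (r in seq_len(m$R)) {
    cat("  class", r, sprintf("(prevalence %.3f)", m$p[r]), "\n")
    print(round(m$pi[, r, ], 3))
  }
  if (!is.null(m$modal_class)) {
    cat("\nModal class sizes:\n")
    print(table(factor(m$modal_class, levels = seq_len(m$R))))
  }
  invisible(x)
}

#' @export
coef.coglca <- function(object, ...) {
  list(p = object$p, pi = object$pi)
}

#' @export
logLik.coglca <- function(object, ...) {
  structure(object$loglik, df = object$q, nobs = object$n_used,
            class = "logLik")
}

#' @export
predict.coglca <- function(object, newdata, type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  post <- posterior(object, newdata)
  if (type == "class") post$modal_class else post$tau
}

#' @export
print.coglca_path <- function(x, ...) {
  cat("Latent-class fit path (k = 1..", nrow(x$indices), ")\n", sep = "")
  print(x$indices, row.names = FALSE)
  invisible(x)
}
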