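#' Restricted log-likelihood of the multivariate random-effects model
#'
#' Evaluates, for a given mean vector and between-study covariance matrix,
#' the restricted log-likelihood of the model in which each study's observed
#' effect sub-vector is normal with mean the corresponding sub-vector of
#' `beta` and covariance `Omega[obs, obs] + S_i`. The REML adjustment
#' `-0.5 * log|sum_i X_i' V_i^-1 X_i|` for estimating the mean is included,
#' so at the generalised-least-squares mean this equals the profiled
#' restricted log-likelihood.
#'
#' @param blocks Per-study blocks from [assemble_blocks()].
#' @param beta Mean vector, one entry per registry level.
#' @param omega Between-study covariance matrix (same dimension as `beta`).
#' @return The restricted log-likelihood (a scalar).
#' @export
mv_restricted_loglik <- function(blocks, beta, omega) {
  d <- length(beta)
  stopifnot(nrow(omega) == d, ncol(omega) == d)
  ldet <- 0
  quad <- 0
  XtVX <- matrix(0, d, d)
  XtX <- matrix(0, d, d)
  n <- 0L
  for (b in blocks) {
    V <- omega[b$idx, b$idx, drop = FALSE] + b$S
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) {
      abort(paste0("singular total covariance for study ", b$study_id))
    }
    r <- b$y - beta[b$idx]
    z <- backsolve(R, r, transpose = TRUE)
    X <- diag(d)[b$idx, , drop = FALSE]
    Zx <- backsolve(R, X, transpose = TRUE)
    ldet <- ldet + 2 * sum(log(diag(R)))
    quad <- quad + sum(z^2)
    XtVX <- XtVX + crossprod(Zx)
    XtX <- XtX + crossprod(X)
    n <- n + length(b$y)
  }
  Rb <- chol(XtVX)
  -0.5 * ((n - d) * log(2 * pi) + ldet + 2 * sum(log(diag(Rb))) + quad) +
    0.5 * as.numeric(determinant(XtX, logarithm = TRUE)$modulus)
}

#' Multivariate random-effects meta-analysis across cut-points or methods
#'
#' Jointly pools the effect estimates at all levels (cut-points and/or
#' measurement methods), allowing each study to report any subset of levels
#' (assumed missing at random). Each study's within-study covariance matrix
#' combines the squared standard errors with the stated (or imputed)
#' within-study covariances; the true level-specific effects are normal
#' around the summary vector with between-study covariance `Omega`,
#' estimated by REML on an unconstrained parameterisation (log-Cholesky for
#' the unstructured case). The correlated levels let sparsely reported
#' levels borrow strength from well-reported ones.
#'
#' @param data A [meta_dataset] or a block list from [assemble_blocks()].
#' @param structure Between-study covariance structure: `"unstructured"`
#'   (level-specific variances, free correlations),
#'   `"common_var_common_corr"` (one variance, one correlation) or `"ar1"`
#'   (variance `tau^2` and correlation `rho^|j-k|` over the ordered levels).
#' @param impute_rho Correlation substituted for unstated within-study
#'   covariances (see [assemble_blocks()]).
#' @param ci_level Confidence level for the per-level Wald intervals.
#' @param n_restarts Number of dispersed optimiser starts (default 3).
#' @return An object of class `meta_mv`: summary effects `beta` with
#'   covariance `vcov`, between-study covariance `omega` (with `tau` and
#'   correlation matrix `corr`), the restricted log-likelihood, per-level
#'   study counts, and convergence/boundary diagnostics. Methods:
#'   [tidy()], [glance()], [prediction_interval()], [autoplot()].
#' @export
#' @examples
#' fit <- meta_mv(apgar_cutpoints())
#' tidy(fit)
meta_mv <- function(data, structure = c("unstructured", "common_var_common_corr", "ar1"),
                    impute_rho = NULL, ci_level = 0.95, n_restarts = 3) {
  structure <- match.arg(structure)
  blocks <- if (inherits(data, "meta_dataset")) {
    assemble_blocks(data, impute_rho = impute_rho)
  } else {
    data
  }
  registry <- attr(blocks, "levels")
  d <- nrow(registry)
  k <- length(blocks)
  if (k < 2L) abort("at least 2 studies are required")
  n_per_level <- vapply(
    seq_len(d),
    function(j) sum(vapply(blocks, function(b) j %in% b$idx, logical(1))),
    integer(1)
  )
  if (any(n_per_level == 0L)) {
    abort(paste0("level '", registry$level[which(n_per_level == 0)[1]], "' is observed in no study"))
  }

  X_list <- lapply(blocks, function(b) diag(d)[b$idx, , drop = FALSE])
  y_list <- lapply(blocks, function(b) b$y)
  S_list <- lapply(blocks, function(b) b$S)
  idx_list <- lapply(blocks, function(b) b$idx)

  obj <- function(theta) {
    Om <- omega_build(theta, structure, d)
    V <- lapply(seq_len(k), function(i) {
      Om[idx_list[[i]], idx_list[[i]], drop = FALSE] + S_list[[i]]
    })
    prof <- gls_profile(V, X_list, y_list, reml = TRUE)
    if (is.null(prof) || !is.finite(prof$loglik)) return(1e10)
    -prof$loglik
  }
  starts <- omega_starts(structure, d, moment_tau2(blocks, d))
  starts <- starts[seq_len(min(length(starts), max(1, n_restarts)))]
  bounds <- omega_bounds(structure, d)
  best <- reml_optimize(obj, starts, lower = bounds$lower, upper = bounds$upper)

  omega <- omega_build(best$par, structure, d)
  dimnames(omega) <- list(registry$level, registry$level)
  V <- lapply(seq_len(k), function(i) {
    omega[idx_list[[i]], idx_list[[i]], drop = FALSE] + S_list[[i]]
  })
  prof <- gls_profile(V, X_list, y_list, reml = TRUE)
  beta <- setNames(prof$beta, registry$level)
  vcov <- prof$cov_beta
  dimnames(vcov) <- dimnames(omega)
  tau <- sqrt(pmax(diag(omega), 0))
  corr <- omega / (tau %o% tau)
  corr[!is.finite(corr)] <- NA_real_
  diag(corr) <- 1
  boundary <- d > 1 && any(abs(corr[upper.tri(corr)]) > 1 - 1e-6, na.rm = TRUE)
  z <- qnorm(1 - (1 - ci_level) / 2)

  base::structure(
    list(
      beta = beta, se = sqrt(diag(vcov)), vcov = vcov,
      ci = tibble(
        level = registry$level,
        lo = beta - z * sqrt(diag(vcov)), hi = beta + z * sqrt(diag(vcov))
      ),
      ci_level = ci_level,
      omega = omega, tau = setNames(tau, registry$level), corr = corr,
      loglik = prof$loglik, k = k, n_levels = d, n_per_level = n_per_level,
      levels = registry, structure = structure,
      converged = TRUE, boundary = boundary, trace = best$trace,
      scale = attr(blocks, "scale") %||% "log_odds"
    ),
    class = "meta_mv"
  )
}

#' @param level Registry level (label or cut-point value) for which the
#'   interval is computed.
#' @rdname prediction_interval
#' @export
prediction_interval.meta_mv <- function(object, level, coverage = 0.95,
                                        n_for_df = object$k, ...) {
  j <- match(as.character(level), object$levels$level)
  if (is.na(j)) abort(paste0("unknown level '", level, "'"))
  out <- pi_from_components(object$beta[j], object$vcov[j, j], object$omega[j, j],
    coverage = coverage, n_for_df = n_for_df
  )
  dplyr::bind_cols(tibble(level = object$levels$level[j]), out)
}

#' Sensitivity of the multivariate fit to assumed within-study correlations
#'
#' Refits the multivariate model over a grid of assumed within-study
#' correlations, substituting each value for the unknown covariances
#' (optionally also overriding the stated ones), and tabulates the summary
#' effects and heterogeneity estimates.
#'
#' @param dataset A [meta_dataset].
#' @param rho_grid Correlations in (-1, 1) to assume in turn.
#' @param structure Passed to [meta_mv()].
#' @param override_observed If `TRUE`, stated within-study covariances are
#'   also replaced by the grid value (otherwise only unstated pairs are).
#' @return A tibble with one row per grid value and level: `rho_assumed`,
#'   `level`, `beta`, `se`, `exp_beta`, `tau`.
#' @export
sensitivity_within_corr <- function(dataset, rho_grid,
                                    structure = "unstructured",
                                    override_observed = FALSE) {
  stopifnot(inherits(dataset, "meta_dataset"))
  if (any(abs(rho_grid) >= 1)) abort("rho_grid values must lie strictly inside (-1, 1)")
  purrr::map_dfr(rho_grid, function(rho) {
    ds <- dataset
    if (override_observed) {
      ds$correlations <- ds$correlations[0, ]
    }
    fit <- suppressWarnings(meta_mv(ds, structure = structure, impute_rho = rho))
    tibble(
      rho_assumed = rho, level = names(fit$beta),
      beta = unname(fit$beta), se = unname(fit$se),
      exp_beta = exp(unname(fit$beta)), tau = unname(fit$tau)
    )
  })
}

#' @export
print.meta_mv <- function(x, ...) {
  cat(
    "Multivariate random-effects meta-analysis (REML, ", x$structure, ")\n",
    "  ", x$k, " studies, ", x$n_levels, " levels\n",
    sep = ""
  )
  print(tidy(x))
  if (x$n_levels > 1) {
    cat("Between-study correlations:\n")
    print(round(x$corr, 3))
    if (x$boundary) cat("note: a between-study correlation sits at the +/-1 boundary\n")
  }
  invisible(x)
}
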