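#' Specify the functional form linking prognostic effect and cut-point
#'
#' The trend model relates the summary log effect to the cut-point value
#' through a transformed covariate: the identity for a linear trend, or a
#' single fractional-polynomial power from \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}
#' (0 denoting the log). A shift is added to the cut-point before negative
#' or log powers so the transform stays defined; `shift = "auto"` uses +1
#' when any cut-point is at or below zero and 0 otherwise.
#'
#' @param family `"linear"` or `"fractional_polynomial"`.
#' @param power Fractional-polynomial power (ignored for linear).
#' @param shift Non-negative constant added to the cut-point before the
#'   power transform, or `"auto"`.
#' @return An object of class `trend_transform`.
#' @export
#' @examples
#' transform_cutpoints(0:3, trend_transform("fractional_polynomial", power = -2))
trend_transform <- function(family = c("linear", "fractional_polynomial"),
                            power = 1, shift = "auto") {
  family <- match.arg(family)
  fp_powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  if (family == "fractional_polynomial" && !power %in% fp_powers) {
    abort(paste0(
      "power must be one of {", paste(fp_powers, collapse = ", "), "}"
    ))
  }
  if (!identical(shift, "auto") && (!is.numeric(shift) || shift < 0)) {
    abort("shift must be a non-negative number or \"auto\"")
  }
  base::structure(
    list(family = family, power = if (family == "linear") 1 else power, shift = shift),
    class = "trend_transform"
  )
}

resolve_shift <- function(spec, x) {
  if (!identical(spec$shift, "auto")) return(spec$shift)
  needs_shift <- spec$family == "fractional_polynomial" && spec$power <= 0
  if (needs_shift && any(x <= 0)) 1 else 0
}

#' Transform cut-point values under a trend specification
#'
#' @param x Cut-point values.
#' @param spec A [trend_transform()].
#' @return The transformed design values `f(x)`.
#' @rdname trend_transform
#' @export
transform_cutpoints <- function(x, spec) {
  stopifnot(inherits(spec, "trend_transform"))
  shift <- resolve_shift(spec, x)
  if (spec$family == "linear") return(x)
  xs <- x + shift
  if (spec$power <= 0 && any(xs <= 0)) {
    abort("shifted cut-points must be strictly positive for negative/log powers")
  }
  if (spec$power == 0) log(xs) else xs^spec$power
}

#' @export
print.trend_transform <- function(x, ...) {
  if (x$family == "linear") {
    cat("<trend_transform> linear\n")
  } else {
    cat(
      "<trend_transform> fractional polynomial, power ", x$power,
      ", shift ", if (identical(x$shift, "auto")) "auto" else x$shift, "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Multivariate meta-analysis with a cut-point trend
#'
#' Fits the random-intercept trend model: each study's effect estimates at
#' its reported cut-points are normal around `alpha_i + gamma * f(x_j)` with
#' the study's within-study covariance matrix, and the study intercepts
#' `alpha_i` are normal around `alpha` with between-study variance
#' `tau_alpha^2`. This replaces the per-level summary means of the general
#' multivariate model by a two-parameter function of the cut-point, which is
#' essential when many cut-points are each reported by few studies.
#' Optionally the slope is also random (independent variance
#' `tau_gamma^2`), and with `by_method = TRUE` each measurement method gets
#' its own fixed intercept and slope (with optionally method-specific
#' intercept variances and a between-method intercept correlation via
#' `group_var = TRUE`).
#'
#' @param data A [meta_dataset] (cut-points required) or a block list from
#'   [assemble_blocks()].
#' @param transform A [trend_transform()]; default linear.
#' @param random_slope Add a between-study variance for the slope.
#' @param by_method Separate fixed intercept and slope per measurement
#'   method.
#' @param group_var With `by_method`, give each method its own intercept
#'   variance and estimate a between-method intercept correlation.
#' @param ci_level Confidence level for Wald intervals on the coefficients.
#' @param impute_rho Passed to [assemble_blocks()] for unstated covariances.
#' @param ml Also run the full maximum-likelihood fit that AIC-based model
#'   comparison needs (default `TRUE`; set `FALSE` to skip it, e.g. inside
#'   simulation loops, in which case `aic` is `NA`).
#' @return An object of class `meta_trend` with `coef` (`alpha`, `gamma`,
#'   or method-specific versions), `vcov`, `tau_alpha` (and `tau_gamma`),
#'   REML and full-ML log-likelihoods, and `aic` (from full ML, comparable
#'   across mean structures). Methods: [tidy()], [glance()],
#'   [predict_cutpoint()], [autoplot()].
#' @export
#' @examples
#' fit <- meta_trend(apgar_cutpoints())
#' glance(fit)
meta_trend <- function(data, transform = trend_transform("linear"),
                       random_slope = FALSE, by_method = FALSE,
                       group_var = FALSE, ci_level = 0.95, impute_rho = NULL,
                       ml = TRUE) {
  stopifnot(inherits(transform, "trend_transform"))
  blocks <- if (inherits(data, "meta_dataset")) {
    assemble_blocks(data, impute_rho = impute_rho)
  } else {
    data
  }
  registry <- attr(blocks, "levels")
  if (any(is.na(registry$cutpoint))) {
    abort("every level needs a numeric cut-point to fit a trend")
  }
  x <- registry$cutpoint
  shift <- resolve_shift(transform, x)
  transform$shift <- shift
  f <- transform_cutpoints(x, transform)
  if (length(unique(f)) < 2L) {
    abort("singular design: fewer than 2 distinct (transformed) cut-points")
  }
  k <- length(blocks)
  if (k < 2L) abort("at least 2 studies are required")

  groups <- if (by_method) registry$method else rep("all", nrow(registry))
  if (by_method && any(is.na(groups))) abort("by_method requires method labels for every level")
  glev <- unique(groups)
  M <- length(glev)

  # fixed-effects design: intercept + slope (per method when by_method)
  make_X <- function(idx) {
    g <- match(groups[idx], glev)
    Xi <- matrix(0, length(idx), 2L * M)
    for (r in seq_along(idx)) {
      Xi[r, g[r]] <- 1
      Xi[r, M + g[r]] <- f[idx[r]]
    }
    Xi
  }
  X_list <- lapply(blocks, function(b) make_X(b$idx))
  Xall <- do.call(rbind, X_list)
  if (qr(Xall)$rank < ncol(Xall)) abort("singular design for the requested mean structure")
  y_list <- lapply(blocks, function(b) b$y)
  idx_list <- lapply(blocks, function(b) b$idx)
  S_list <- lapply(blocks, function(b) b$S)

  # random-effects part of the marginal covariance
  n_int <- if (group_var && M > 1L) M + M * (M - 1L) / 2L else 1L
  n_var <- n_int + as.integer(random_slope)
  make_V <- function(theta, i) {
    idx <- idx_list[[i]]
    di <- length(idx)
    if (group_var && M > 1L) {
      Og <- omega_build(theta[seq_len(n_int)], "unstructured", M)
      Z <- matrix(0, di, M)
      Z[cbind(seq_len(di), match(groups[idx], glev))] <- 1
      Vi <- Z %*% Og %*% t(Z)
    } else {
      Vi <- matrix(exp(2 * theta[1]), di, di)
    }
    if (random_slope) {
      fg <- f[idx]
      Vi <- Vi + exp(2 * theta[n_var]) * (fg %o% fg)
    }
    Vi + S_list[[i]]
  }
  fit_at <- function(reml) {
    obj <- function(theta) {
      V <- lapply(seq_len(k), function(i) make_V(theta, i))
      prof <- gls_profile(V, X_list, y_list, reml = reml)
      if (is.null(prof) || !is.finite(prof$loglik)) return(1e10)
      -prof$loglik
    }
    tau0 <- sqrt(max(mean(moment_tau2(blocks, nrow(registry))), 1e-3))
    base_starts <- if (group_var && M > 1L) {
      list(
        c(rep(log(tau0), M), rep(0, n_int - M)),
        c(rep(-2, M), rep(0, n_int - M)),
        c(rep(log(tau0) + 1, M), rep(0.3, n_int - M))
      )
    } else {
      list(log(tau0), -2, log(tau0) + 1)
    }
    starts <- lapply(base_starts, function(s) c(s, if (random_slope) -2))
    lower <- rep(-15, n_var)
    upper <- rep(5, n_var)
    if (group_var && M > 1L) {
      lower[seq_len(n_int)[-seq_len(M)]] <- -40
      upper[seq_len(n_int)[-seq_len(M)]] <- 40
    }
    best <- reml_optimize(obj, starts, lower = lower, upper = upper)
    V <- lapply(seq_len(k), function(i) make_V(best$par, i))
    prof <- gls_profile(V, X_list, y_list, reml = reml)
    list(theta = best$par, prof = prof, trace = best$trace)
  }

  reml_fit <- fit_at(TRUE)
  ml_fit <- if (ml) fit_at(FALSE) else NULL

  nm <- if (M == 1L) {
    c("alpha", "gamma")
  } else {
    c(paste0("alpha_", glev), paste0("gamma_", glev))
  }
  coefs <- setNames(reml_fit$prof$beta, nm)
  vc <- reml_fit$prof$cov_beta
  dimnames(vc) <- list(nm, nm)
  theta <- reml_fit$theta
  tau_alpha2 <- if (group_var && M > 1L) {
    diag(omega_build(theta[seq_len(n_int)], "unstructured", M))
  } else {
    exp(2 * theta[1])
  }
  tau_gamma2 <- if (random_slope) exp(2 * theta[n_var]) else NULL
  n_par <- ncol(Xall) + n_var
  z <- qnorm(1 - (1 - ci_level) / 2)

  base::structure(
    list(
      coef = coefs, vcov = vc, se = sqrt(diag(vc)),
      ci = tibble(
        term = nm, lo = coefs - z * sqrt(diag(vc)), hi = coefs + z * sqrt(diag(vc))
      ),
      ci_level = ci_level,
      tau_alpha2 = tau_alpha2, tau_alpha = sqrt(tau_alpha2),
      tau_gamma2 = tau_gamma2,
      tau_gamma = if (is.null(tau_gamma2)) NULL else sqrt(tau_gamma2),
      loglik = reml_fit$prof$loglik,
      loglik_ml = if (ml) ml_fit$prof$loglik else NA_real_,
      n_par = n_par,
      aic = if (ml) -2 * ml_fit$prof$loglik + 2 * n_par else NA_real_,
      transform = transform, random_slope = random_slope,
      by_method = by_method, groups = glev,
      k = k, n_obs = sum(lengths(y_list)),
      x_range = range(x), levels = registry,
      points = purrr::map_dfr(blocks, function(b) {
        tibble(
          study_id = b$study_id, level = b$levels,
          cutpoint = registry$cutpoint[b$idx], y = unname(b$y)
        )
      }),
      scale = attr(blocks, "scale") %||% "log_odds",
      converged = TRUE, trace = reml_fit$trace
    ),
    class = "meta_trend"
  )
}

#' Summary effect at chosen cut-points from a fitted trend
#'
#' Evaluates `alpha_hat + gamma_hat * f(x)` with a delta-method confidence
#' interval and a t-based prediction interval (adding the between-study
#' intercept variance, and slope variance if present, under the square
#' root; degrees of freedom `k - 2`). Cut-points outside the observed range
#' are refused unless `allow_extrapolation = TRUE`, since the fitted
#' function has no support beyond the data.
#'
#' @param object A `meta_trend` fit.
#' @param x Cut-point values at which to summarise.
#' @param coverage Coverage for the confidence and prediction intervals.
#' @param allow_extrapolation Permit `x` outside the observed cut-point
#'   range.
#' @param method With `by_method` fits, which method's curve to evaluate.
#' @return A tibble with one row per `x`: `estimate`, `se`, `lo`, `hi`,
#'   `pi_lo`, `pi_hi` on the log scale and exponentiated counterparts.
#' @export
predict_cutpoint <- function(object, x, coverage = 0.95,
                             allow_extrapolation = FALSE, method = NULL) {
  stopifnot(inherits(object, "meta_trend"))
  outside <- x < object$x_range[1] | x > object$x_range[2]
  if (any(outside) && !allow_extrapolation) {
    abort(paste0(
      "cut-point ", x[which(outside)[1]], " lies outside the observed range [",
      object$x_range[1], ", ", object$x_range[2],
      "]; the fitted trend should not be extrapolated (override with allow_extrapolation = TRUE)"
    ))
  }
  f <- transform_cutpoints(x, object$transform)
  M <- length(object$groups)
  if (M > 1L) {
    method <- method %||% object$groups[1]
    g <- match(method, object$groups)
    if (is.na(g)) abort(paste0("unknown method '", method, "'"))
    tau_a2 <- if (length(object$tau_alpha2) > 1L) object$tau_alpha2[g] else object$tau_alpha2
  } else {
    g <- 1L
    tau_a2 <- object$tau_alpha2
  }
  X <- matrix(0, length(x), 2L * M)
  X[, g] <- 1
  X[, M + g] <- f
  est <- unname(drop(X %*% object$coef))
  se <- unname(sqrt(rowSums((X %*% object$vcov) * X)))
  crit <- qnorm(1 - (1 - coverage) / 2)
  df <- object$k - 2
  if (df <= 0) abort("prediction interval needs k - 2 > 0 studies")
  t_crit <- qt(1 - (1 - coverage) / 2, df = df)
  pi_sd <- sqrt(se^2 + tau_a2 +
    if (is.null(object$tau_gamma2)) 0 else object$tau_gamma2 * f^2)
  tibble(
    x = x, estimate = est, se = se,
    lo = est - crit * se, hi = est + crit * se,
    pi_lo = est - t_crit * pi_sd, pi_hi = est + t_crit * pi_sd,
    exp_estimate = exp(est),
    exp_lo = exp(est - crit * se), exp_hi = exp(est + crit * se),
    exp_pi_lo = exp(est - t_crit * pi_sd), exp_pi_hi = exp(est + t_crit * pi_sd)
  )
}

#' Compare candidate cut-point transforms by AIC
#'
#' Fits each candidate transform by full maximum likelihood with an
#' identical random-effects structure and ranks them by
#' `AIC = -2 loglik + 2 (number of parameters)`. REML likelihoods are not
#' comparable across mean structures, hence the ML refit. Candidates whose
#' transform is undefined on the observed cut-point range are skipped with
#' a warning. Ties keep the input order.
#'
#' @param data A [meta_dataset] or block list.
#' @param candidates A list of [trend_transform()] objects (at least 2
#'   recommended).
#' @param ... Passed to [meta_trend()].
#' @return A tibble ranked by AIC with columns `rank`, `family`, `power`,
#'   `shift`, `loglik_ml`, `n_par`, `aic`, and the fitted objects in a
#'   list-column `fit`.
#' @export
select_function <- function(data, candidates, ...) {
  if (!length(candidates)) abort("no candidate transforms supplied")
  rows <- purrr::imap(candidates, function(spec, i) {
    fit <- tryCatch(meta_trend(data, transform = spec, ...), error = function(e) {
      warn(paste0("candidate ", i, " skipped: ", conditionMessage(e)))
      NULL
    })
    if (is.null(fit)) return(NULL)
    tibble(
      family = spec$family, power = fit$transform$power,
      shift = fit$transform$shift, loglik_ml = fit$loglik_ml,
      n_par = fit$n_par, aic = fit$aic, fit = list(fit)
    )
  })
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0L) abort("every candidate failed")
  out <- out[order(out$aic), ]
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}

#' @export
print.meta_trend <- function(x, ...) {
  cat("Cut-point trend meta-analysis (REML), k =", x$k, "studies\n")
  print(x$transform)
  est <- cbind(estimate = x$coef, se = x$se, lo = x$ci$lo, hi = x$ci$hi)
  print(round(est, 4))
  cat(sprintf("  tau_alpha = %.3f", x$tau_alpha[1]))
  if (!is.null(x$tau_gamma)) cat(sprintf(", tau_gamma = %.3f", x$tau_gamma))
  cat(sprintf("; AIC (ML) = %.1f\n", x$aic))
  invisible(x)
}
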