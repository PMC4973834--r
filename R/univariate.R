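#' Univariate random-effects meta-analysis
#'
#' Pools one effect estimate per study under the two-level normal model
#' `y_i ~ N(theta_i, s_i^2)`, `theta_i ~ N(beta, tau^2)`. The between-study
#' variance is estimated by restricted maximum likelihood (default) or the
#' DerSimonian-Laird moment estimator; the summary effect is the
#' inverse-variance weighted mean at the estimated `tau^2`, with a Wald
#' confidence interval using normal quantiles.
#'
#' @param data A data frame with columns `y` and `se` (one row per study),
#'   or a [meta_dataset] (then `level` selects which level to pool).
#' @param method `"REML"` (default) or `"DL"`.
#' @param level For a [meta_dataset] with several levels, the level label
#'   (or cut-point value) to analyse.
#' @param ci_level Confidence level for the Wald interval.
#' @return An object of class `meta_uni` with components `beta` (summary log
#'   effect), `se`, `ci`, `tau2`, `tau`, `k`, `Q`, `I2`, `loglik` and the
#'   data used. Methods: [tidy()], [glance()], [prediction_interval()].
#' @export
#' @examples
#' apgar <- apgar_cutpoints()
#' meta_uni(apgar, level = 3)
meta_uni <- function(data, method = c("REML", "DL"), level = NULL,
                     ci_level = 0.95) {
  method <- match.arg(method)
  scale <- "log_odds"
  level_lab <- NULL
  if (inherits(data, "meta_dataset")) {
    scale <- data$scale
    eff <- data$effects
    if (!is.null(level)) {
      level <- as.character(level)
      eff <- eff[eff$level == level, ]
      if (nrow(eff) == 0L) abort(paste0("no records at level '", level, "'"))
      level_lab <- level
    } else if (dplyr::n_distinct(eff$level) > 1L) {
      abort("dataset has several levels; pick one with `level = `")
    } else {
      level_lab <- eff$level[1]
    }
    df <- eff
  } else {
    df <- as_tibble(data)
    if (!all(c("y", "se") %in% names(df))) abort("data needs columns 'y' and 'se'")
    if (any(df$se <= 0)) abort("all standard errors must be positive")
  }
  y <- df$y
  s2 <- df$se^2
  k <- length(y)
  if (k < 2L) abort("at least 2 studies are required")

  # fixed-effect heterogeneity statistics
  w_fe <- 1 / s2
  beta_fe <- sum(w_fe * y) / sum(w_fe)
  Q <- sum(w_fe * (y - beta_fe)^2)
  I2 <- max(0, (Q - (k - 1)) / Q) * 100

  if (method == "DL") {
    tau2 <- max(0, (Q - (k - 1)) / (sum(w_fe) - sum(w_fe^2) / sum(w_fe)))
    conv <- list(converged = TRUE)
  } else {
    opt <- uni_reml_tau2(y, s2)
    tau2 <- opt$tau2
    conv <- opt
  }
  w <- 1 / (s2 + tau2)
  beta <- sum(w * y) / sum(w)
  var_beta <- 1 / sum(w)
  se_beta <- sqrt(var_beta)
  z <- qnorm(1 - (1 - ci_level) / 2)
  ll <- uni_restricted_loglik(tau2, y, s2)

  structure(
    list(
      beta = beta, se = se_beta, var_beta = var_beta,
      ci = c(lo = beta - z * se_beta, hi = beta + z * se_beta),
      ci_level = ci_level,
      tau2 = tau2, tau = sqrt(tau2), k = k, Q = Q, I2 = I2,
      loglik = ll, method = method, scale = scale, level = level_lab,
      converged = isTRUE(conv$converged), data = df
    ),
    class = "meta_uni"
  )
}

# profile restricted log-likelihood of the univariate model at a given tau2
uni_restricted_loglik <- function(tau2, y, s2) {
  v <- s2 + tau2
  w <- 1 / v
  beta <- sum(w * y) / sum(w)
  # + 0.5 log(k) term: same restricted-likelihood convention as gls_profile
  -0.5 * ((length(y) - 1) * log(2 * pi) + sum(log(v)) + log(sum(w)) +
    sum(w * (y - beta)^2)) + 0.5 * log(length(y))
}

# REML tau2: quasi-Newton on log(tau2) from dispersed starts, with an
# explicit check of the tau2 = 0 boundary
uni_reml_tau2 <- function(y, s2) {
  obj <- function(theta) -uni_restricted_loglik(exp(theta), y, s2)
  starts <- list(log(max(var(y) - mean(s2), 0.01)), -4, 1)
  best <- reml_optimize(obj, starts, lower = -30, upper = 10,
    control = list(iter.max = 200, rel.tol = 1e-10))
  tau2 <- exp(best$par)
  ll0 <- uni_restricted_loglik(0, y, s2)
  if (ll0 >= -best$objective - 1e-10 || tau2 < 1e-10) tau2 <- 0
  list(tau2 = tau2, converged = TRUE, trace = best$trace)
}

#' Cochran's Q and the I-squared statistic
#'
#' @param data A data frame with columns `y` and `se`, one row per study.
#' @return A one-row tibble with `k`, `Q` (fixed-effect heterogeneity
#'   statistic) and `I2` (percentage of total variability attributed to
#'   between-study heterogeneity, `max(0, (Q - (k - 1))/Q) * 100`).
#' @export
heterogeneity <- function(data) {
  df <- as_tibble(data)
  if (!all(c("y", "se") %in% names(df))) abort("data needs columns 'y' and 'se'")
  k <- nrow(df)
  if (k < 2L) abort("at least 2 studies are required")
  w <- 1 / df$se^2
  beta_fe <- sum(w * df$y) / sum(w)
  Q <- sum(w * (df$y - beta_fe)^2)
  tibble(k = k, Q = Q, I2 = max(0, (Q - (k - 1)) / Q) * 100)
}

#' Prediction interval for the effect in a new study
#'
#' Computes `beta_hat +/- t_{N-2} * sqrt(tau2_hat + Var(beta_hat))`, the
#' interval within which the true effect of a new study/population is
#' expected to lie, accounting for between-study heterogeneity. A
#' t critical value with `N - 2` degrees of freedom (N = number of studies)
#' is used to acknowledge the uncertainty in the heterogeneity estimate.
#'
#' @param object A fitted `meta_uni` or `meta_mv` object.
#' @param ... Passed to methods.
#' @return A one-row tibble with the interval on the log scale (`lo`, `hi`),
#'   exponentiated (`exp_lo`, `exp_hi`), plus `df` and `t_crit`.
#' @export
prediction_interval <- function(object, ...) {
  UseMethod("prediction_interval")
}

#' @param coverage Coverage probability, default 0.95.
#' @param n_for_df Number of studies used for the degrees of freedom
#'   (`df = n_for_df - 2`); defaults to the number of studies in the fit.
#' @rdname prediction_interval
#' @export
prediction_interval.meta_uni <- function(object, coverage = 0.95,
                                         n_for_df = object$k, ...) {
  pi_from_components(object$beta, object$var_beta, object$tau2,
    coverage = coverage, n_for_df = n_for_df
  )
}

pi_from_components <- function(beta, var_beta, tau2, coverage, n_for_df) {
  beta <- unname(beta)
  var_beta <- unname(var_beta)
  tau2 <- unname(tau2)
  if (n_for_df < 3) abort("prediction interval needs at least 3 studies (df = N - 2 > 0)")
  df <- n_for_df - 2
  t_crit <- qt(1 - (1 - coverage) / 2, df = df)
  half <- t_crit * sqrt(tau2 + var_beta)
  tibble(
    lo = beta - half, hi = beta + half,
    exp_lo = exp(beta - half), exp_hi = exp(beta + half),
    df = df, t_crit = t_crit
  )
}

#' Random-effects meta-regression on study-level covariates
#'
#' Fits `y_i ~ N(theta_i, s_i^2)`, `theta_i ~ N(x_i' coef, tau^2)` by REML,
#' typically with the cut-point value as covariate, so that the summary
#' effect at cut-point `x` is `alpha + gamma * x`.
#'
#' @param data A data frame with columns `y`, `se` and the covariates named
#'   in `formula`.
#' @param formula One-sided formula for the mean model, e.g. `~ cutpoint`.
#' @return An object of class `meta_regress` with `coef`, `vcov`, `tau2`,
#'   `loglik`, `k`. Use [predict_effect()] for fitted effects at new
#'   covariate values.
#' @export
meta_regress <- function(data, formula = ~cutpoint) {
  df <- as_tibble(data)
  if (!all(c("y", "se") %in% names(df))) abort("data needs columns 'y' and 'se'")
  X <- stats::model.matrix(formula, data = df)
  if (nrow(X) != nrow(df)) abort("covariates contain missing values")
  p <- ncol(X)
  k <- nrow(df)
  if (k <= p + 1L) abort("too few studies for the number of coefficients")
  if (qr(X)$rank < p) {
    abort("rank-deficient design (is a covariate constant?)")
  }
  y_list <- as.list(df$y)
  X_list <- lapply(seq_len(k), function(i) X[i, , drop = FALSE])
  s2 <- df$se^2
  obj <- function(theta) {
    tau2 <- exp(theta)
    V <- lapply(s2, function(s) matrix(s + tau2, 1, 1))
    prof <- gls_profile(V, X_list, y_list, reml = TRUE)
    if (is.null(prof)) return(1e10)
    -prof$loglik
  }
  best <- reml_optimize(obj, list(-1, -4, 1), lower = -30, upper = 10)
  tau2 <- exp(best$par)
  V0 <- lapply(s2, function(s) matrix(s, 1, 1))
  prof0 <- gls_profile(V0, X_list, y_list, reml = TRUE)
  if (!is.null(prof0) && prof0$loglik >= -best$objective - 1e-10) tau2 <- 0
  if (tau2 < 1e-10) tau2 <- 0
  V <- lapply(s2, function(s) matrix(s + tau2, 1, 1))
  prof <- gls_profile(V, X_list, y_list, reml = TRUE)
  coefs <- setNames(prof$beta, colnames(X))
  vc <- prof$cov_beta
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(
      coef = coefs, vcov = vc, tau2 = tau2, tau = sqrt(tau2),
      loglik = prof$loglik, k = k, formula = formula, data = df
    ),
    class = "meta_regress"
  )
}

#' Summary effect at a covariate value from a meta-regression
#'
#' @param object A `meta_regress` fit.
#' @param newdata Data frame of covariate values at which to evaluate the
#'   fitted mean.
#' @param ci_level Confidence level.
#' @return A tibble with `estimate`, `se`, `lo`, `hi` (log scale) and the
#'   exponentiated counterparts.
#' @export
predict_effect <- function(object, newdata, ci_level = 0.95) {
  stopifnot(inherits(object, "meta_regress"))
  X <- stats::model.matrix(object$formula, data = as_tibble(newdata))
  est <- unname(drop(X %*% object$coef))
  se <- unname(sqrt(rowSums((X %*% object$vcov) * X)))
  z <- qnorm(1 - (1 - ci_level) / 2)
  tibble(
    estimate = est, se = se, lo = est - z * se, hi = est + z * se,
    exp_estimate = exp(est), exp_lo = exp(est - z * se), exp_hi = exp(est + z * se)
  )
}

#' @export
print.meta_uni <- function(x, ...) {
  cat("Random-effects meta-analysis (", x$method, "), k = ", x$k, "\n", sep = "")
  if (!is.null(x$level)) cat("Level:", x$level, "\n")
  cat(sprintf(
    "  summary log effect: %.3f (SE %.3f), %g%% CI [%.3f, %.3f]\n",
    x$beta, x$se, 100 * x$ci_level, x$ci[1], x$ci[2]
  ))
  cat(sprintf(
    "  exp scale: %.2f [%.2f, %.2f]\n",
    exp(x$beta), exp(x$ci[1]), exp(x$ci[2])
  ))
  cat(sprintf("  tau = %.3f, Q = %.2f, I2 = %.1f%%\n", x$tau, x$Q, x$I2))
  invisible(x)
}

#' @export
print.meta_regress <- function(x, ...) {
  cat("Random-effects meta-regression, k =", x$k, "\n")
  print(round(x$coef, 4))
  cat(sprintf("  tau = %.3f\n", x$tau))
  invisible(x)
}
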