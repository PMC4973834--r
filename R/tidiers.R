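# broom-style tidiers for the fitted objects

#' @export
tidy.meta_uni <- function(x, exponentiate = FALSE, ...) {
  est <- x$beta
  lo <- x$ci[["lo"]]
  hi <- x$ci[["hi"]]
  out <- tibble(
    term = x$level %||% "summary",
    estimate = est, std.error = x$se,
    statistic = est / x$se, p.value = 2 * pnorm(-abs(est / x$se)),
    conf.low = lo, conf.high = hi
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @export
glance.meta_uni <- function(x, ...) {
  tibble(
    k = x$k, tau2 = x$tau2, tau = x$tau, Q = x$Q, I2 = x$I2,
    logLik = x$loglik, method = x$method
  )
}

#' @export
tidy.meta_mv <- function(x, exponentiate = FALSE, ...) {
  est <- unname(x$beta)
  se <- unname(x$se)
  out <- tibble(
    level = x$levels$level, estimate = est, std.error = se,
    statistic = est / se, p.value = 2 * pnorm(-abs(est / se)),
    conf.low = x$ci$lo, conf.high = x$ci$hi,
    tau = unname(x$tau), n_studies = x$n_per_level
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @export
glance.meta_mv <- function(x, ...) {
  tibble(
    k = x$k, n_levels = x$n_levels, logLik = x$loglik,
    structure = x$structure, boundary = x$boundary, converged = x$converged
  )
}

#' @export
tidy.meta_trend <- function(x, ...) {
  est <- unname(x$coef)
  se <- unname(x$se)
  tibble(
    term = names(x$coef), estimate = est, std.error = se,
    statistic = est / se, p.value = 2 * pnorm(-abs(est / se)),
    conf.low = x$ci$lo, conf.high = x$ci$hi
  )
}

#' @export
glance.meta_trend <- function(x, ...) {
  tibble(
    k = x$k, n_obs = x$n_obs, tau_alpha = x$tau_alpha[1],
    tau_gamma = if (is.null(x$tau_gamma)) NA_real_ else x$tau_gamma,
    logLik = x$loglik, logLik_ml = x$loglik_ml, AIC = x$aic,
    family = x$transform$family, power = x$transform$power
  )
}

#' @export
tidy.meta_regress <- function(x, ...) {
  est <- unname(x$coef)
  se <- sqrt(diag(x$vcov))
  z <- qnorm(0.975)
  tibble(
    term = names(x$coef), estimate = est, std.error = se,
    statistic = est / se, p.value = 2 * pnorm(-abs(est / se)),
    conf.low = est - z * se, conf.high = est + z * se
  )
}

#' @export
glance.meta_regress <- function(x, ...) {
  tibble(k = x$k, tau2 = x$tau2, tau = x$tau, logLik = x$loglik)
}

#' @export
tidy.boot_corr <- function(x, ...) {
  lab <- rownames(x$corr)
  pairs <- which(upper.tri(x$corr), arr.ind = TRUE)
  tibble(
    level_a = lab[pairs[, 1]], level_b = lab[pairs[, 2]],
    rho = x$corr[pairs], cov = x$cov[pairs]
  )
}
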