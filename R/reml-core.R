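# Shared restricted-likelihood machinery for the multivariate and trend
# models. All models share the marginal form
#   y_i ~ N(X_i beta, V_i(theta)),  V_i = (between-study part) + S_i,
# with beta profiled out by generalised least squares, so only the
# variance parameters theta are optimised numerically.

# Evaluate the (restricted or full) profile log-likelihood for a set of
# per-study covariance matrices. Returns NULL when a matrix is not positive
# definite so optimisers can treat the point as infeasible.
gls_profile <- function(V_list, X_list, y_list, reml = TRUE) {
  p <- ncol(X_list[[1]])
  XtVX <- matrix(0, p, p)
  XtX <- matrix(0, p, p)
  XtVy <- numeric(p)
  quad <- 0
  ldet <- 0
  n <- 0L
  for (i in seq_along(y_list)) {
    R <- tryCatch(chol(V_list[[i]]), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    ldet <- ldet + 2 * sum(log(diag(R)))
    Zx <- backsolve(R, X_list[[i]], transpose = TRUE)
    zy <- backsolve(R, y_list[[i]], transpose = TRUE)
    XtVX <- XtVX + crossprod(Zx)
    XtX <- XtX + crossprod(X_list[[i]])
    XtVy <- XtVy + drop(crossprod(Zx, zy))
    quad <- quad + sum(zy^2)
    n <- n + length(y_list[[i]])
  }
  Rb <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(Rb)) return(NULL)
  beta <- backsolve(Rb, backsolve(Rb, XtVy, transpose = TRUE))
  rss <- quad - sum(XtVy * beta)
  ll <- if (reml) {
    # the + 0.5 log|X'X| term makes the restricted likelihood invariant to
    # linear reparameterisation of the mean design (the usual convention)
    -0.5 * ((n - p) * log(2 * pi) + ldet + 2 * sum(log(diag(Rb))) + rss) +
      0.5 * as.numeric(determinant(XtX, logarithm = TRUE)$modulus)
  } else {
    -0.5 * (n * log(2 * pi) + ldet + rss)
  }
  list(
    loglik = ll, beta = drop(beta), cov_beta = chol2inv(Rb),
    n = n, p = p
  )
}

# Quasi-Newton maximisation of the profile (restricted) log-likelihood over
# an unconstrained variance parameterisation, with dispersed restarts.
reml_optimize <- function(objective, starts, lower, upper,
                          control = list(iter.max = 500, rel.tol = 1e-10)) {
  best <- NULL
  traces <- list()
  for (s in seq_along(starts)) {
    fit <- tryCatch(
      nlminb(starts[[s]], objective,
        lower = lower, upper = upper,
        control = control
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$objective)) next
    traces[[length(traces) + 1L]] <- list(
      start = starts[[s]], objective = -fit$objective,
      convergence = fit$convergence, message = fit$message
    )
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
  }
  if (is.null(best)) {
    abort("restricted-likelihood optimisation failed from every start")
  }
  best$trace <- traces
  best
}

# --- between-study covariance parameterisations -----------------------------

omega_npar <- function(structure, d) {
  switch(structure,
    unstructured = d + d * (d - 1L) / 2L,
    common_var_common_corr = if (d == 1L) 1L else 2L,
    ar1 = if (d == 1L) 1L else 2L,
    abort(paste0("unknown between-study structure '", structure, "'"))
  )
}

# theta -> Omega (d x d PSD matrix)
omega_build <- function(theta, structure, d) {
  if (d == 1L) {
    return(matrix(exp(2 * theta[1]), 1, 1))
  }
  switch(structure,
    unstructured = {
      L <- matrix(0, d, d)
      diag(L) <- exp(theta[seq_len(d)])
      L[lower.tri(L)] <- theta[-seq_len(d)]
      tcrossprod(L)
    },
    common_var_common_corr = {
      tau2 <- exp(2 * theta[1])
      lo <- -1 / (d - 1) + 1e-6
      rho <- lo + (1 - 1e-6 - lo) * plogis(theta[2])
      tau2 * ((1 - rho) * diag(d) + rho)
    },
    ar1 = {
      tau2 <- exp(2 * theta[1])
      rho <- tanh(theta[2])
      tau2 * rho^abs(outer(seq_len(d), seq_len(d), "-"))
    }
  )
}

# starting parameter vectors: method-of-moments-flavoured, near-zero, inflated
omega_starts <- function(structure, d, tau2_init) {
  tau_init <- sqrt(pmax(tau2_init, 1e-4))
  if (d == 1L) {
    return(list(log(tau_init[1]), -2, log(tau_init[1]) + 1))
  }
  switch(structure,
    unstructured = list(
      c(log(tau_init), rep(0, d * (d - 1L) / 2L)),
      c(rep(-2, d), rep(0, d * (d - 1L) / 2L)),
      c(log(tau_init) + 1, rep(0.5, d * (d - 1L) / 2L))
    ),
    list(
      c(log(mean(tau_init)), 0),
      c(-2, 0),
      c(log(mean(tau_init)) + 1, 1.5)
    )
  )
}

omega_bounds <- function(structure, d) {
  np <- omega_npar(structure, d)
  if (structure == "unstructured" && d > 1L) {
    list(
      lower = c(rep(-15, d), rep(-40, np - d)),
      upper = c(rep(5, d), rep(40, np - d))
    )
  } else {
    list(lower = c(-15, -15)[seq_len(np)], upper = c(5, 15)[seq_len(np)])
  }
}

# crude per-level DerSimonian-Laird tau2 used to seed the optimiser
moment_tau2 <- function(blocks, n_levels) {
  vapply(seq_len(n_levels), function(j) {
    y <- unlist(lapply(blocks, function(b) b$y[b$idx == j]))
    s2 <- unlist(lapply(blocks, function(b) diag(b$S)[b$idx == j]))
    if (length(y) < 2L) return(0.05)
    w <- 1 / s2
    bfe <- sum(w * y) / sum(w)
    Q <- sum(w * (y - bfe)^2)
    max(0, (Q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  }, numeric(1))
}
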