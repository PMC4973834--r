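test_that("restricted log-likelihood matches a dense matrix oracle", {
  ds <- toy_bivariate()
  blocks <- assemble_blocks(ds)
  beta <- c(0.6, 0.5)
  omega <- matrix(c(0.3, 0.1, 0.1, 0.25), 2)
  expect_equal(
    mv_restricted_loglik(blocks, beta, omega),
    dense_reml_loglik(blocks, beta, omega),
    tolerance = 1e-10
  )
  # one study, one level: collapses to the scalar restricted likelihood
  one <- meta_dataset(tibble::tibble(study_id = c("a", "b"), cutpoint = 1,
    y = c(0.4, 0.6), se = c(0.2, 0.3)))
  b1 <- assemble_blocks(one)
  expect_equal(
    mv_restricted_loglik(b1, 0.5, matrix(0.1, 1, 1)),
    dense_reml_loglik(b1, 0.5, matrix(0.1, 1, 1)),
    tolerance = 1e-10
  )
})

test_that("the REML optimum dominates a brute-force grid and local perturbations", {
  sim <- simulate_effects(8,
    beta = c(1, 0.8),
    omega = matrix(c(0.2, 0.08, 0.08, 0.15), 2), seed = 101
  )
  fit <- meta_mv(sim$dataset)
  blocks <- assemble_blocks(sim$dataset)
  rho_hat <- fit$corr[1, 2]
  taus1 <- seq(0.01, 0.6, length.out = 21)
  taus2 <- seq(0.01, 0.6, length.out = 21)
  grid_max <- max(vapply(taus1, function(t1) {
    max(vapply(taus2, function(t2) {
      om <- matrix(c(t1, rho_hat * sqrt(t1 * t2), rho_hat * sqrt(t1 * t2), t2), 2)
      prof_beta <- tryCatch(
        cutmeta:::gls_profile(
          lapply(blocks, function(b) om[b$idx, b$idx, drop = FALSE] + b$S),
          lapply(blocks, function(b) diag(2)[b$idx, , drop = FALSE]),
          lapply(blocks, function(b) b$y)
        )$loglik,
        error = function(e) -Inf
      )
      prof_beta
    }, numeric(1)))
  }, numeric(1)))
  expect_gte(fit$loglik, grid_max - 1e-3)
  # fitted point beats nearby perturbations of the full parameter vector
  for (eps in c(0.05, -0.05)) {
    om_pert <- fit$omega + diag(eps * c(1, 0.7))
    if (min(eigen(om_pert, only.values = TRUE)$values) > 0) {
      expect_gte(
        fit$loglik,
        mv_restricted_loglik(blocks, fit$beta, om_pert) - 1e-8
      )
    }
  }
})

test_that("published two-cut-point fit is reproduced and agrees with metafor", {
  fit <- meta_mv(apgar)
  expect_equal(exp(unname(fit$beta)), c(8.69, 7.93), tolerance = 0.01)
  expect_equal(unname(fit$tau), c(0.72, 0.560), tolerance = 0.01)
  expect_true(fit$boundary)
  expect_gt(fit$corr[1, 2], 0.999)

  skip_if_not_installed("metafor")
  d <- apgar$effects
  blocks <- assemble_blocks(apgar)
  V <- lapply(blocks, function(b) unname(b$S))
  ref <- metafor::rma.mv(y ~ 0 + factor(level), V = V,
    random = ~ factor(level) | study_id, struct = "UN",
    data = d[order(match(d$study_id, vapply(blocks, `[[`, character(1), "study_id"))), ],
    method = "REML", control = list(rel.tol = 1e-10)
  )
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-3)
  expect_equal(unname(fit$tau)^2, unname(ref$tau2), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
})

test_that("published two-method fit is reproduced (hazard-ratio example)", {
  fit <- meta_mv(mvd)
  expect_equal(exp(fit$beta[["chalkley"]]), 1.051, tolerance = 0.005)
  expect_equal(exp(fit$beta[["all_vessels"]]), 1.030, tolerance = 0.005)
  expect_equal(fit$tau[["all_vessels"]], 0.077, tolerance = 0.01)
  expect_lt(fit$tau[["chalkley"]], 0.02)
  u_ch <- meta_uni(mvd, level = "chalkley")
  u_av <- meta_uni(mvd, level = "all_vessels")
  expect_equal(exp(u_ch$beta), 1.049, tolerance = 0.005)
  expect_equal(exp(u_av$beta), 1.032, tolerance = 0.005)
})

test_that("with one level the multivariate fit reduces to the univariate fit", {
  one <- meta_dataset(apgar$effects[apgar$effects$level == "3", ])
  fit_mv1 <- meta_mv(one)
  fit_u <- meta_uni(one)
  expect_equal(unname(fit_mv1$beta), fit_u$beta, tolerance = 1e-6)
  expect_equal(unname(fit_mv1$tau)^2, fit_u$tau2, tolerance = 1e-6)
  expect_equal(fit_mv1$loglik, fit_u$loglik, tolerance = 1e-8)
})

test_that("uncorrelated non-overlapping levels separate into univariate fits", {
  eff <- tibble::tibble(
    study_id = c("a", "b", "c", "d", "e", "f"),
    cutpoint = c(1, 1, 1, 2, 2, 2),
    y = c(0.5, 0.7, 0.6, 1.1, 1.3, 1.2),
    se = c(0.2, 0.25, 0.3, 0.2, 0.25, 0.3)
  )
  ds <- meta_dataset(eff)
  fit <- meta_mv(ds)
  u1 <- meta_uni(ds, level = 1)
  u2 <- meta_uni(ds, level = 2)
  expect_equal(unname(fit$beta), c(u1$beta, u2$beta), tolerance = 1e-4)
})

test_that("relabelling levels permutes the estimates consistently", {
  # rename "all_vessels" so it sorts after "chalkley": the registry order
  # flips, and all estimates must flip with it
  eff <- mvd$effects
  eff$method[eff$method == "all_vessels"] <- "zz_vessels"
  cors <- mvd$correlations
  cors$level_b[cors$level_b == "all_vessels"] <- "zz_vessels"
  cors$cov <- NA_real_
  swapped <- meta_dataset(eff, cors, scale = "log_hazard")
  f1 <- meta_mv(mvd)
  f2 <- meta_mv(swapped)
  expect_equal(f2$levels$level, c("chalkley", "zz_vessels"))
  expect_equal(unname(f2$beta), unname(f1$beta)[2:1], tolerance = 1e-5)
  expect_equal(unname(f2$tau), unname(f1$tau)[2:1], tolerance = 1e-3)
})

test_that("structured between-study covariances are estimable", {
  sim <- simulate_effects(20,
    beta = c(1, 0.9, 0.8),
    omega = 0.2 * (0.6 * diag(3) + 0.4), cutpoints = 1:3, seed = 5
  )
  fit_cs <- meta_mv(sim$dataset, structure = "common_var_common_corr")
  expect_equal(dim(fit_cs$omega), c(3L, 3L))
  expect_equal(fit_cs$omega[1, 1], fit_cs$omega[2, 2], tolerance = 1e-8)
  fit_ar <- meta_mv(sim$dataset, structure = "ar1")
  rho <- fit_ar$corr[1, 2]
  expect_equal(fit_ar$corr[1, 3], rho^2, tolerance = 1e-6)
  # unstructured nests both: its restricted likelihood is at least as high
  fit_un <- meta_mv(sim$dataset)
  expect_gte(fit_un$loglik + 1e-6, fit_cs$loglik)
  expect_gte(fit_un$loglik + 1e-6, fit_ar$loglik)
})

test_that("parameter recovery on complete synthetic data (k = 50)", {
  truth_beta <- c(2.2, 2.0)
  omega <- matrix(c(0.49, 0.9 * 0.7 * 0.6, 0.9 * 0.7 * 0.6, 0.36), 2)
  n_rep <- 40
  est <- t(vapply(seq_len(n_rep), function(r) {
    sim <- simulate_effects(50, beta = truth_beta, omega = omega,
      cutpoints = c(3, 6), seed = 7000 + r)
    unname(meta_mv(sim$dataset, n_restarts = 1)$beta)
  }, numeric(2)))
  for (j in 1:2) {
    mc_se <- sd(est[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(est[, j]) - truth_beta[j]), 2 * mc_se + 0.01)
  }
})

test_that("multivariate prediction intervals follow the t construction", {
  fit <- meta_mv(apgar)
  pi3 <- prediction_interval(fit, 3)
  by_hand <- fit$beta[["3"]] +
    c(-1, 1) * qt(0.975, 8) * sqrt(fit$omega[1, 1] + fit$vcov[1, 1])
  expect_equal(c(pi3$lo, pi3$hi), by_hand, ignore_attr = TRUE)
  # zero heterogeneity: interval equals the t-based confidence interval
  eff <- tibble::tibble(study_id = letters[1:4], cutpoint = 1,
    y = rep(0.5, 4), se = rep(0.2, 4))
  f0 <- meta_mv(meta_dataset(eff))
  p0 <- prediction_interval(f0, 1)
  expect_equal(p0$hi - p0$lo, 2 * qt(0.975, 2) * f0$se[[1]], tolerance = 1e-4)
  expect_error(prediction_interval(fit, 99), "unknown level")
})

test_that("assumed within-study correlations barely move the summary (sensitivity)", {
  tab <- sensitivity_within_corr(mvd, c(0.3, 0.6, 0.9), override_observed = TRUE)
  hrs <- matrix(tab$exp_beta, nrow = 2)
  expect_lt(max(hrs[1, ]) - min(hrs[1, ]), 0.01)
  expect_lt(max(hrs[2, ]) - min(hrs[2, ]), 0.01)
  # a rho = 0 grid on unstated pairs reproduces the default-zero analysis
  ds <- meta_dataset(apgar$effects) # no correlation rows at all
  f0 <- suppressWarnings(meta_mv(ds))
  t0 <- suppressWarnings(sensitivity_within_corr(ds, 0))
  expect_equal(t0$beta, unname(f0$beta), tolerance = 1e-6)
  expect_error(sensitivity_within_corr(mvd, 1.5), "strictly inside")
})
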