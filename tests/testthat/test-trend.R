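test_that("cut-point transforms follow their definitions and guard their domains", {
  expect_equal(transform_cutpoints(3, trend_transform("linear")), 3)
  fp2 <- trend_transform("fractional_polynomial", power = -2, shift = 1)
  expect_equal(transform_cutpoints(c(0, 1, 2), fp2), c(1, 0.25, 1 / 9))
  fp0 <- trend_transform("fractional_polynomial", power = 0, shift = 1)
  expect_equal(transform_cutpoints(c(0, 1), fp0), log(c(1, 2)))
  expect_error(
    transform_cutpoints(0, trend_transform("fractional_polynomial", power = -2, shift = 0)),
    "strictly positive"
  )
  # auto shift engages only when a cut-point is at or below zero
  auto <- trend_transform("fractional_polynomial", power = -2)
  expect_equal(transform_cutpoints(c(1, 2), auto), c(1, 0.25))
  expect_equal(transform_cutpoints(c(0, 1), auto), c(1, 0.25))
  expect_error(trend_transform("fractional_polynomial", power = 1.7), "power")
})

test_that("a single distinct cut-point is refused as a singular design", {
  eff <- tibble::tibble(study_id = c("a", "b"), cutpoint = 3,
    y = c(0.5, 0.7), se = c(0.2, 0.2))
  expect_error(meta_trend(meta_dataset(eff)), "singular design")
})

test_that("null slope data reduce to the pooled univariate mean", {
  sim <- simulate_effects(30, beta = rep(1.2, 3),
    omega = 0.09 * ((1 - 1e-6) * matrix(1, 3, 3) + 1e-6 * diag(3)),
    cutpoints = c(1, 4, 7), rho_within = 0.5, seed = 21)
  fit <- meta_trend(sim$dataset)
  expect_lt(abs(fit$coef[["gamma"]]), 2 * fit$se[2])
  expect_equal(fit$coef[["alpha"]] + 4 * fit$coef[["gamma"]], 1.2, tolerance = 0.15)
})

test_that("with homogeneous data a saturated linear trend matches the joint per-level fit", {
  # two levels, no heterogeneity: intercept + slope saturate the two means,
  # so the trend and the general multivariate model give the same GLS answer
  eff <- tibble::tibble(
    study_id = rep(c("a", "b", "c"), each = 2),
    cutpoint = rep(c(1, 2), 3),
    y = rep(c(0.8, 0.6), 3),
    se = rep(c(0.2, 0.25), 3)
  )
  cors <- tibble::tibble(study_id = c("a", "b", "c"), level_a = "1",
    level_b = "2", rho = 0.4)
  ds <- meta_dataset(eff, cors)
  ft <- meta_trend(ds)
  fm <- meta_mv(ds)
  pred <- predict_cutpoint(ft, c(1, 2))
  expect_equal(pred$estimate, unname(fm$beta), tolerance = 1e-4)
})

test_that("trend parameters are recovered on data simulated from the model", {
  alpha <- 2.4
  gamma <- -0.07
  tau_a <- 0.7
  x <- 0:5
  sim <- simulate_effects(40, beta = alpha + gamma * x,
    omega = tau_a^2 * ((1 - 1e-8) * matrix(1, 6, 6) + 1e-8 * diag(6)),
    cutpoints = x, rho_within = 0.5, se_range = c(0.15, 0.45), seed = 99)
  fit <- meta_trend(sim$dataset)
  expect_equal(fit$coef[["alpha"]], alpha, tolerance = 3 * fit$se[1] / alpha)
  expect_lt(abs(fit$coef[["gamma"]] - gamma), 3 * fit$se[2])
  expect_equal(fit$tau_alpha, tau_a, tolerance = 0.4)
})

test_that("predictions interpolate, refuse extrapolation, and add heterogeneity to the PI", {
  fit <- meta_trend(apgar)
  pred <- predict_cutpoint(fit, c(3, 6))
  # linear family on monotone data: prediction lies between per-level
  # univariate extremes
  u3 <- meta_uni(apgar, level = 3)$beta
  u6 <- meta_uni(apgar, level = 6)$beta
  expect_true(all(pred$estimate >= min(u3, u6) - 0.5 &
    pred$estimate <= max(u3, u6) + 0.5))
  expect_true(all(pred$pi_lo < pred$lo & pred$pi_hi > pred$hi))
  expect_equal(pred$pi_hi - pred$estimate,
    qt(0.975, fit$k - 2) * sqrt(pred$se^2 + fit$tau_alpha2),
    tolerance = 1e-10
  )
  expect_error(predict_cutpoint(fit, 9), "extrapolated")
  expect_s3_class(predict_cutpoint(fit, 9, allow_extrapolation = TRUE), "tbl_df")
})

test_that("model selection by ML-based AIC identifies strong curvature", {
  x <- 0:5
  f <- transform_cutpoints(x, trend_transform("fractional_polynomial", power = -2))
  sim <- simulate_effects(40, beta = 1 + 2.5 * f,
    omega = 0.04 * ((1 - 1e-8) * matrix(1, 6, 6) + 1e-8 * diag(6)),
    cutpoints = x, rho_within = 0.5, se_range = c(0.1, 0.25), seed = 12)
  sel <- select_function(sim$dataset, list(
    trend_transform("linear"),
    trend_transform("fractional_polynomial", power = -2)
  ))
  expect_equal(sel$family[1], "fractional_polynomial")
  expect_lt(sel$aic[1], sel$aic[2])
  # identical duplicate candidates tie and keep input order
  dup <- select_function(sim$dataset, list(
    trend_transform("linear"), trend_transform("linear")
  ))
  expect_equal(dup$aic[1], dup$aic[2])
  one <- select_function(sim$dataset, list(trend_transform("linear")))
  expect_equal(one$rank, 1L)
})

test_that("AIC is invariant to affine rescaling of the covariate", {
  eff <- apgar$effects
  scaled <- eff
  scaled$cutpoint <- scaled$cutpoint * 10
  cors <- apgar$correlations
  cors2 <- cors
  cors2$level_a <- "30"
  cors2$level_b <- "60"
  cors2$cov <- NA_real_
  f1 <- meta_trend(apgar)
  f2 <- meta_trend(meta_dataset(scaled, cors2))
  expect_equal(f2$aic, f1$aic, tolerance = 1e-6)
  expect_equal(f2$coef[["gamma"]], f1$coef[["gamma"]] / 10, tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("method-stratified trends give each method its own intercept and slope", {
  x <- c(1, 2, 3)
  f <- x
  sim_a <- simulate_effects(12, beta = 1.5 - 0.2 * f,
    omega = 0.05 * ((1 - 1e-8) * matrix(1, 3, 3) + 1e-8 * diag(3)),
    cutpoints = x, methods = rep("m1", 3), seed = 31)
  sim_b <- simulate_effects(12, beta = 0.8 - 0.05 * f,
    omega = 0.05 * ((1 - 1e-8) * matrix(1, 3, 3) + 1e-8 * diag(3)),
    cutpoints = x, methods = rep("m2", 3), seed = 32)
  eff_b <- sim_b$dataset$effects
  eff_b$study_id <- paste0("b_", eff_b$study_id)
  cor_b <- sim_b$dataset$correlations
  cor_b$study_id <- paste0("b_", cor_b$study_id)
  cor_b$cov <- NA_real_
  cor_a <- sim_a$dataset$correlations
  cor_a$cov <- NA_real_
  ds <- meta_dataset(
    dplyr::bind_rows(sim_a$dataset$effects, eff_b),
    dplyr::bind_rows(cor_a, cor_b)
  )
  fit <- meta_trend(ds, by_method = TRUE)
  expect_setequal(
    names(fit$coef),
    c("alpha_m1", "alpha_m2", "gamma_m1", "gamma_m2")
  )
  expect_lt(abs(fit$coef[["gamma_m1"]] - (-0.2)), 3 * fit$se[["gamma_m1"]] + 0.05)
  expect_lt(abs(fit$coef[["gamma_m2"]] - (-0.05)), 3 * fit$se[["gamma_m2"]] + 0.05)
})
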