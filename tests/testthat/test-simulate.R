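test_that("model-based simulation is seed-reproducible and moment-faithful", {
  om <- matrix(c(0.49, 0.378, 0.378, 0.36), 2)
  s1 <- simulate_effects(200, beta = c(2.2, 2.0), omega = om,
    cutpoints = c(3, 6), seed = 61)
  s2 <- simulate_effects(200, beta = c(2.2, 2.0), omega = om,
    cutpoints = c(3, 6), seed = 61)
  expect_identical(s1$dataset$effects, s2$dataset$effects)
  expect_identical(s1$truth$theta, s2$truth$theta)

  # marginal variance of y at a level = omega_jj + average within variance
  eff <- s1$dataset$effects
  y3 <- eff$y[eff$level == "3"]
  s3 <- eff$se[eff$level == "3"]
  expect_equal(mean(y3), 2.2, tolerance = 0.15)
  expect_equal(var(y3), om[1, 1] + mean(s3^2), tolerance = 0.25)

  # no-heterogeneity limit: spread of y is driven by the se's alone
  s0 <- simulate_effects(400, beta = 0.5, omega = matrix(0, 1, 1),
    se_range = c(0.2, 0.2), seed = 62)
  expect_equal(var(s0$dataset$effects$y), 0.04, tolerance = 0.15)

  # diagonal omega and zero within-study correlation: no cross-level correlation
  sd0 <- simulate_effects(400, beta = c(1, 1), omega = diag(c(0.3, 0.3)),
    rho_within = 0, cutpoints = c(1, 2), seed = 63)
  w <- tidyr::pivot_wider(sd0$dataset$effects[c("study_id", "level", "y")],
    names_from = "level", values_from = "y")
  expect_lt(abs(cor(w$`1`, w$`2`)), 2.5 / sqrt(400))

  expect_error(
    simulate_effects(10, beta = c(0, 0), omega = matrix(c(1, 2, 2, 1), 2), seed = 1),
    "positive semi-definite"
  )
})

test_that("recovery of known multivariate parameters at large k", {
  om <- matrix(c(0.49, 0.9 * 0.7 * 0.6, 0.9 * 0.7 * 0.6, 0.36), 2)
  sim <- simulate_effects(200, beta = c(2.2, 2.0), omega = om,
    cutpoints = c(3, 6), seed = 64)
  fit <- meta_mv(sim$dataset, n_restarts = 1)
  expect_equal(unname(fit$beta), c(2.2, 2.0), tolerance = 0.15)
  expect_equal(unname(fit$tau), c(0.7, 0.6), tolerance = 0.15)
  expect_equal(fit$corr[1, 2], 0.9, tolerance = 0.12)
})

test_that("cohort simulation produces consistent tables and sensible odds ratios", {
  sim <- simulate_cohorts(5, cutpoints = c(-1, 0, 1), n_range = c(300, 600),
    intercept = -1.5, slope = -1, seed = 71)
  for (i in seq_along(sim$tables)) {
    tab <- sim$tables[[i]]
    expect_true(all(tab$a + tab$c == tab$a[1] + tab$c[1]))
    ints <- tables_to_intervals(tab) # consistency: no error
    expect_equal(sum(ints$events) + sum(ints$nonevents), sim$truth$n[i])
  }
  # negative slope: low factor values are higher risk, so every log odds
  # ratio is positive; per-cut-point means track the true log odds ratio
  # obtained by numerical integration of the logistic-normal model
  true_lor <- function(cp, int, sl) {
    f1 <- function(f) plogis(int + sl * f) * dnorm(f)
    ple <- stats::integrate(f1, -10, cp)$value / pnorm(cp)
    pgt <- stats::integrate(f1, cp, 10)$value / (1 - pnorm(cp))
    log(ple / (1 - ple)) - log(pgt / (1 - pgt))
  }
  # inverse-variance weighting keeps continuity-corrected near-empty tail
  # tables (huge variance) from dominating the comparison
  eff <- sim$dataset$effects
  wmean_by_cut <- vapply(c(-1, 0, 1), function(cp) {
    s <- eff[eff$cutpoint == cp, ]
    sum(s$y / s$se^2) / sum(1 / s$se^2)
  }, numeric(1))
  expect_true(all(wmean_by_cut > 0))
  for (j in 1:3) {
    expect_equal(wmean_by_cut[j], true_lor(c(-1, 0, 1)[j], -1.5, -1),
      tolerance = 0.3
    )
  }

  # flat outcome model: log odds ratios scatter around zero
  flat <- simulate_cohorts(6, cutpoints = 0, n_range = c(400, 600),
    intercept = -1, slope = 0, seed = 72)
  expect_lt(abs(mean(flat$dataset$effects$y)), 0.15)

  expect_error(simulate_cohorts(2, cutpoints = 50, seed = 1), "support")
  expect_error(simulate_cohorts(2, cutpoints = 0, n_range = c(5, 10), seed = 1), "at least 20")
})

test_that("missingness mechanisms delete what they claim to delete", {
  om <- matrix(c(0.49, 0.378, 0.378, 0.36), 2)
  sim <- simulate_effects(40, beta = c(0.5, 0.4), omega = om / 4,
    cutpoints = c(1, 2), seed = 81)
  ds <- sim$dataset

  # zero probability: identity
  same <- apply_missingness(ds, "MCAR", prob = 0, seed = 1)
  expect_equal(same$effects, ds$effects)

  # forced pattern: level 2 kept only in the protected study
  forced <- suppressWarnings(
    apply_missingness(ds, "MAR_by_level", prob = c("2" = 1), protect = "s01", seed = 2)
  )
  lvl2 <- forced$effects[forced$effects$level == "2", ]
  expect_equal(lvl2$study_id, "s01")
  # correlation rows referencing deleted records are dropped
  expect_true(all(forced$correlations$study_id == "s01"))

  # MNAR by significance: every deleted record was non-significant, and all
  # significant records survive
  thin <- apply_missingness(ds, "MNAR_significance", prob = 1, alpha = 0.05, seed = 3)
  z <- qnorm(0.975)
  kept_keys <- paste(thin$effects$study_id, thin$effects$level)
  all_keys <- paste(ds$effects$study_id, ds$effects$level)
  deleted <- ds$effects[!all_keys %in% kept_keys, ]
  expect_true(all(abs(deleted$y) / deleted$se < z))
  expect_true(all(abs(thin$effects$y) / thin$effects$se >= z))
})

test_that("under selective (MNAR) reporting the joint model is less biased than per-level pooling", {
  # level-2 results are deleted whenever non-significant: the surviving
  # level-2 estimates over-state the effect; correlation with the fully
  # reported level 1 partially corrects this in the joint fit
  om <- matrix(c(0.3^2, 0.9 * 0.3 * 0.3, 0.9 * 0.3 * 0.3, 0.3^2), 2)
  truth <- c(0.5, 0.4)
  n_rep <- 500
  res <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_effects(14, beta = truth, omega = om, cutpoints = c(1, 2),
      rho_within = 0.6, se_range = c(0.15, 0.45), seed = 90000 + r)
    thin <- tryCatch(
      apply_missingness(sim$dataset, "MNAR_significance", prob = 0.8,
        level = "2", protect = "s01", seed = 90000 + r),
      warning = function(w) NULL
    )
    if (is.null(thin)) return(c(NA_real_, NA_real_))
    eff2 <- thin$effects[thin$effects$level == "2", ]
    if (nrow(eff2) < 2) return(c(NA_real_, NA_real_))
    uni <- meta_uni(eff2)$beta
    mv <- tryCatch(unname(meta_mv(thin, n_restarts = 1)$beta[2]),
      error = function(e) NA_real_)
    c(uni, mv)
  }, numeric(2))
  ok <- stats::complete.cases(t(res))
  expect_gt(sum(ok), 300)
  bias_uni <- res[1, ok] - truth[2]
  bias_mv <- res[2, ok] - truth[2]
  # one-sided Monte-Carlo comparison: the univariate bias (away from the
  # null) exceeds the multivariate bias
  expect_gt(mean(bias_uni), 0)
  dif <- bias_uni - bias_mv
  expect_gt(mean(dif) / (sd(dif) / sqrt(length(dif))), qnorm(0.95))
})
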