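# Synthetic-data generators with the exact statistical structure the
# models assume: study-level effects drawn from the multivariate normal
# hierarchy, and cohort-level binary data from a logistic model in a
# continuous factor, dichotomised at ordered cut-points.

mvn_draw <- function(n, mean, sigma) {
  d <- length(mean)
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    abort("covariance matrix is not positive semi-definite")
  }
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- matrix(rnorm(n * d), d, n)
  t(mean + rt %*% z)
}

#' Simulate study-level effect estimates from the multivariate hierarchy
#'
#' Draws true study effects `theta_i ~ N(beta, omega)` and observed
#' estimates `y_i ~ N(theta_i, S_i)`, where each study's standard errors
#' are drawn log-uniformly over `se_range` and its within-study correlation
#' is `rho_within`. Levels are labelled by `cutpoints` (or `methods`).
#'
#' @param k Number of studies (>= 2).
#' @param beta True summary log effects, one per level.
#' @param omega True between-study covariance matrix.
#' @param se_range Range for the log-uniform within-study standard errors.
#' @param rho_within Common within-study correlation used to build each
#'   study's `S_i` (also written to the correlation table).
#' @param cutpoints Optional numeric labels for the levels (default
#'   `seq_along(beta)`).
#' @param methods Optional method labels instead of cut-points.
#' @param seed Integer seed (required; the generator has no global state).
#' @param scale `"log_odds"` or `"log_hazard"`.
#' @return A list with `$dataset` (a [meta_dataset]) and `$truth` (the
#'   generating parameters, the latent `theta` draws and the seed).
#' @export
#' @examples
#' sim <- simulate_effects(10, beta = c(2.2, 2.0),
#'   omega = matrix(c(0.49, 0.38, 0.38, 0.36), 2), seed = 1)
#' sim$dataset
simulate_effects <- function(k, beta, omega, se_range = c(0.1, 0.5),
                             rho_within = 0.5, cutpoints = NULL,
                             methods = NULL, seed,
                             scale = c("log_odds", "log_hazard")) {
  if (missing(seed)) abort("an explicit integer seed is required")
  scale <- match.arg(scale)
  if (k < 2) abort("k must be at least 2")
  d <- length(beta)
  omega <- as.matrix(omega)
  stopifnot(nrow(omega) == d, ncol(omega) == d)
  if (abs(rho_within) >= 1) abort("rho_within must lie strictly inside (-1, 1)")
  if (is.null(cutpoints) && is.null(methods)) cutpoints <- seq_len(d)

  res <- with_preserved_seed(seed, {
    theta <- mvn_draw(k, beta, omega)
    se <- matrix(
      exp(runif(k * d, log(se_range[1]), log(se_range[2]))), k, d
    )
    R <- (1 - rho_within) * diag(d) + rho_within
    y <- t(vapply(seq_len(k), function(i) {
      Si <- R * (se[i, ] %o% se[i, ])
      drop(mvn_draw(1, theta[i, ], Si))
    }, numeric(d)))
    list(theta = theta, se = se, y = y)
  })

  lev_cut <- if (is.null(cutpoints)) rep(NA_real_, d) else cutpoints
  lev_meth <- if (is.null(methods)) rep(NA_character_, d) else methods
  effects <- tibble(
    study_id = rep(sprintf("s%02d", seq_len(k)), each = d),
    cutpoint = rep(lev_cut, k), method = rep(lev_meth, k),
    y = as.vector(t(res$y)), se = as.vector(t(res$se))
  )
  lev_lab <- derive_level(lev_cut, lev_meth)
  correlations <- NULL
  if (d > 1L) {
    pairs <- which(upper.tri(diag(d)), arr.ind = TRUE)
    correlations <- tibble(
      study_id = rep(sprintf("s%02d", seq_len(k)), each = nrow(pairs)),
      level_a = rep(lev_lab[pairs[, 1]], k),
      level_b = rep(lev_lab[pairs[, 2]], k),
      rho = rho_within, provenance = "imputed"
    )
  }
  dataset <- meta_dataset(effects, correlations, scale = scale)
  list(
    dataset = dataset,
    truth = list(
      beta = beta, omega = omega, theta = res$theta,
      rho_within = rho_within, se_range = se_range, seed = seed
    )
  )
}

#' Simulate patient cohorts with a continuous prognostic factor
#'
#' For each study, draws a cohort of subjects with a normally distributed
#' factor and a binary outcome from a logistic model in the factor, then
#' tabulates the 2x2 tables at each requested cut-point and derives the
#' corresponding log odds ratios and standard errors (with continuity
#' correction where needed). The tables feed [boot_within_corr()]; the
#' derived estimates feed the meta-analysis models.
#'
#' @param k Number of studies.
#' @param cutpoints Ordered cut-points, inside the factor's support.
#' @param n_range Range of cohort sizes (uniform integer draw, min 20).
#' @param factor_mean,factor_sd Distribution of the continuous factor.
#' @param intercept,slope Logistic outcome model
#'   `logit P(event) = intercept + slope * factor`. A negative slope makes
#'   low factor values prognostic of the event (odds ratios above 1 for the
#'   at-or-below group).
#' @param seed Integer seed.
#' @return A list with `$tables` (per-study tibbles of 2x2 counts),
#'   `$dataset` (a [meta_dataset] of the derived log odds ratios; records
#'   where a cut-point leaves one group empty are dropped) and `$truth`.
#' @export
simulate_cohorts <- function(k, cutpoints, n_range = c(100, 500),
                             factor_mean = 0, factor_sd = 1,
                             intercept = -2, slope = -1, seed) {
  if (missing(seed)) abort("an explicit integer seed is required")
  if (min(n_range) < 20) abort("cohort sizes must be at least 20")
  p0 <- plogis(intercept)
  if (p0 <= 0 || p0 >= 1) abort("baseline risk must lie in (0, 1)")
  cutpoints <- sort(cutpoints)
  lo <- factor_mean - 6 * factor_sd
  hi <- factor_mean + 6 * factor_sd
  if (any(cutpoints <= lo) || any(cutpoints >= hi)) {
    abort("cut-points fall outside the effective support of the factor")
  }

  sim <- with_preserved_seed(seed, {
    lapply(seq_len(k), function(i) {
      n <- sample(seq(n_range[1], n_range[2]), 1L)
      f <- rnorm(n, factor_mean, factor_sd)
      ev <- rbinom(n, 1L, plogis(intercept + slope * f))
      tab <- tibble(
        cutpoint = cutpoints,
        a = vapply(cutpoints, function(cp) sum(ev == 1L & f <= cp), integer(1)),
        b = vapply(cutpoints, function(cp) sum(ev == 0L & f <= cp), integer(1)),
        c = vapply(cutpoints, function(cp) sum(ev == 1L & f > cp), integer(1)),
        d = vapply(cutpoints, function(cp) sum(ev == 0L & f > cp), integer(1))
      )
      list(n = n, tables = tab)
    })
  })

  study_ids <- sprintf("s%02d", seq_len(k))
  tables <- setNames(lapply(sim, `[[`, "tables"), study_ids)
  effects <- purrr::map_dfr(seq_len(k), function(i) {
    tab <- tables[[i]]
    ok <- (tab$a + tab$b) > 0 & (tab$c + tab$d) > 0
    purrr::map_dfr(which(ok), function(r) {
      cells <- continuity_correct_v(c(
        a = tab$a[r], b = tab$b[r], c = tab$c[r], d = tab$d[r]
      ))
      est <- log_or_cells(cells)
      tibble(
        study_id = study_ids[i], cutpoint = tab$cutpoint[r],
        y = est["lor"], se = sqrt(est["var"])
      )
    })
  })
  if (nrow(effects) == 0L) abort("no usable 2x2 tables were generated")
  dataset <- meta_dataset(effects, scale = "log_odds")
  list(
    tables = tables, dataset = dataset,
    truth = list(
      cutpoints = cutpoints, n = vapply(sim, `[[`, numeric(1), "n"),
      factor_mean = factor_mean, factor_sd = factor_sd,
      intercept = intercept, slope = slope, seed = seed
    )
  )
}

#' Delete level results according to a missingness mechanism
#'
#' Thins a dataset's effect records to emulate unreported cut-points or
#' measurement methods: completely at random (`"MCAR"`), with a
#' level-specific probability (`"MAR_by_level"`), or selectively by
#' statistical significance (`"MNAR_significance"`: results whose Wald test
#' is non-significant at `alpha` are deleted with probability `prob`;
#' significant results are always retained). Correlation rows referencing a
#' deleted record are dropped with it.
#'
#' @param dataset A [meta_dataset].
#' @param mechanism One of `"MCAR"`, `"MAR_by_level"`, `"MNAR_significance"`.
#' @param prob Deletion probability. For `"MAR_by_level"` this may be a
#'   named vector (names = level labels); unnamed values apply to all
#'   levels listed in `level`.
#' @param level Optional level label(s) the deletion is restricted to.
#' @param alpha Significance threshold for `"MNAR_significance"`.
#' @param protect Study ids whose records are never deleted.
#' @param seed Integer seed.
#' @return A thinned [meta_dataset]. Warns if a level loses all its studies.
#' @export
apply_missingness <- function(dataset,
                              mechanism = c("MCAR", "MAR_by_level", "MNAR_significance"),
                              prob = 0.5, level = NULL, alpha = 0.05,
                              protect = NULL, seed) {
  stopifnot(inherits(dataset, "meta_dataset"))
  mechanism <- match.arg(mechanism)
  if (missing(seed)) abort("an explicit integer seed is required")
  if (any(prob < 0 | prob > 1)) abort("deletion probabilities must lie in [0, 1]")
  eff <- dataset$effects
  n <- nrow(eff)

  p_del <- rep(0, n)
  if (mechanism == "MCAR") {
    sel <- if (is.null(level)) rep(TRUE, n) else eff$level %in% as.character(level)
    p_del[sel] <- prob
  } else if (mechanism == "MAR_by_level") {
    if (!is.null(names(prob))) {
      p_del <- unname(prob[eff$level])
      p_del[is.na(p_del)] <- 0
    } else {
      sel <- if (is.null(level)) rep(TRUE, n) else eff$level %in% as.character(level)
      p_del[sel] <- prob
    }
  } else {
    z <- qnorm(1 - alpha / 2)
    nonsig <- abs(eff$y) / eff$se < z
    sel <- if (is.null(level)) nonsig else nonsig & eff$level %in% as.character(level)
    p_del[sel] <- prob
  }
  if (!is.null(protect)) p_del[eff$study_id %in% as.character(protect)] <- 0

  keep <- with_preserved_seed(seed, runif(n) >= p_del)
  kept <- eff[keep, ]
  if (nrow(kept) == 0L) abort("missingness mechanism deleted every record")
  lost <- setdiff(dataset$levels$level, kept$level)
  if (length(lost)) {
    warn(paste0(
      "level(s) ", paste(lost, collapse = ", "),
      " now have zero studies; multivariate fits will fail downstream"
    ))
  }
  cors <- dataset$correlations
  if (nrow(cors)) {
    key <- paste(kept$study_id, kept$level)
    cors <- cors[paste(cors$study_id, cors$level_a) %in% key &
      paste(cors$study_id, cors$level_b) %in% key, ]
    cors$cov <- NA_real_ # re-derived from rho against the retained records
  }
  meta_dataset(kept, cors, scale = dataset$scale, impute_rho = dataset$impute_rho)
}
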