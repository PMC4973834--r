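---
title: "Meta-analysis of prognostic factors across cut-points and measurement methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of prognostic factors across cut-points and measurement methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutmeta)
```

## The problem

A prognostic factor is any measure associated, among people with a given
condition, with the risk of a later outcome. Primary studies rarely report
the factor the same way: continuous factors are dichotomised at different
cut-points, and different measurement methods are in use. A naive
meta-analysis that pools one estimate per study produces a summary that
refers to no particular cut-point or method; taking only one result per
study throws information away; and using several results per study without
care ignores that estimates from the same patients are correlated.

cutmeta implements a coherent toolbox for this situation:

* **univariate random-effects synthesis** per cut-point/method, with
  heterogeneity statistics and *t*-based prediction intervals
  (`meta_uni()`, `heterogeneity()`, `prediction_interval()`);
* **joint (multivariate) random-effects synthesis** over all cut-points
  and/or methods with study-specific within-study covariance matrices and a
  between-study covariance matrix `Omega` estimated by REML (`meta_mv()`);
* **trend models** that replace per-cut-point means by a linear or
  fractional-polynomial function of the cut-point (`meta_trend()`,
  `predict_cutpoint()`, `select_function()`);
* **within-study correlation machinery**: reconstruction of
  participant-level data from cumulative 2x2 tables and non-parametric
  bootstrap of the joint distribution of log odds ratios
  (`tables_to_intervals()`, `boot_within_corr()`), the sparse-cell
  continuity correction (`continuity_correct()`), and the patient-level
  correlation approximation (`approx_cov_from_patient_corr()`);
* **simulators** that generate data with exactly the structure the models
  assume (`simulate_effects()`, `simulate_cohorts()`,
  `apply_missingness()`).

## Models

### One result per study

With `k` studies each contributing one log odds/hazard ratio `y_i` with
known variance `s_i^2`,

$$y_i \sim N(\theta_i, s_i^2), \qquad \theta_i \sim N(\beta, \tau^2).$$

`meta_uni()` estimates `tau^2` by REML (default) or DerSimonian–Laird and
returns the inverse-variance weighted summary at the estimated `tau^2` with
a normal-quantile Wald CI. Because a heterogeneous summary refers to no
single population, the more useful quantity is the **prediction interval**

$$\hat\beta \pm t_{N-2}\sqrt{\hat\tau^2 + \widehat{\mathrm{Var}}(\hat\beta)},$$

whose *t* quantile (df = number of studies minus 2) acknowledges the
uncertainty in `tau^2`. `meta_regress()` adds study-level covariates (e.g.
the cut-point value) to the mean.

### Multiple results per study

When study `i` reports estimates at a subset of the `T` registered levels,
its observed vector is modelled as

$$\mathbf{y}_i \sim N(\boldsymbol\theta_i, S_i), \qquad
  \boldsymbol\theta_i \sim N(\boldsymbol\beta, \Omega),$$

where `S_i` holds the squared standard errors on the diagonal and the
within-study covariances off it, and `Omega` is the between-study
covariance of the true level-specific effects. Missing levels are handled
by per-study dimension reduction under a missing-at-random assumption;
correlation lets a sparsely reported level *borrow strength* from
well-reported ones, which is why the joint model can move a level's summary
substantially relative to its univariate synthesis (the packaged
`apgar_cutpoints()` example moves the cut-point-6 odds ratio from 11.6 to
7.9).

`meta_mv()` maximises the restricted likelihood over an unconstrained
parameterisation: log-Cholesky for unstructured `Omega`, or two parameters
for the common-variance/common-correlation and AR(1) structures. The AR(1)
correlation decays as `rho^|j-k|` over the *ordered cut-point index*
(ordering by value, not spacing) — the structure is a pragmatic middle
ground, not a claim about the metric of the cut-point scale.

### A functional cut-point trend

With many cut-points, the unstructured model has too many parameters.
`meta_trend()` fits

$$y_{ij} \sim N(\alpha_i + \gamma f(x_j), S_i), \qquad
  \alpha_i \sim N(\alpha, \tau_\alpha^2),$$

with `f` the identity (linear trend) or a single fractional-polynomial
power from {-2, -1, -0.5, 0, 0.5, 1, 2, 3} (0 = log). A shift is added to
the cut-point before negative/log powers; with `shift = "auto"` it is +1
exactly when some cut-point is at or below 0 (scores that start at 0 are
common), else 0. Random slopes are off by default: with most studies
reporting one or two cut-points the slope variance is rarely estimable, and
when estimable it is often 0. With `by_method = TRUE` each measurement
method receives its own fixed intercept and slope (and optionally its own
intercept variance plus a between-method intercept correlation), covering
the combined method-by-cut-point setting.

`predict_cutpoint()` returns `alpha + gamma f(x)` with a delta-method CI
and a prediction interval that adds `tau_alpha^2` (and the slope variance,
if any) under the square root, using df = k − 2. Prediction outside the
observed cut-point range is a hard error unless
`allow_extrapolation = TRUE`: the fitted function has no support beyond the
data, and the shape is typically driven by the few studies reporting many
cut-points.

`select_function()` compares candidate transforms by AIC computed from a
**full maximum-likelihood** refit with an identical random-effects
structure; REML likelihoods are not comparable across mean structures, so
REML is used only for the reported estimates. Ties keep input order;
candidates whose transform is undefined on the data are skipped with a
warning.

## Within-study correlations

The joint models need the within-study covariance of each pair of estimates
from the same patients. Publications rarely report it. Three supported
routes:

1. **Bootstrap from reconstructed participant data.** For unadjusted odds
   ratios, the cumulative 2x2 tables at ordered cut-points determine the
   number of events and non-events in every interval between adjacent
   cut-points (`tables_to_intervals()`; the reconstruction is validated by
   exact re-aggregation). `boot_within_corr()` resamples subjects with
   replacement and recomputes all log odds ratios per replicate. Replicates
   where a cut-point empties one side of the split entirely are redrawn (a
   declared convention; capped at 10x the replicate count), and replicate
   tables with a zero cell get the continuity correction below. By default
   the **bootstrap covariance** of the log odds ratios is what enters the
   model; `as_correlation_table(use = "rho")` switches to bootstrap
   correlation combined with the analytic standard errors, for sensitivity.
2. **Patient-level correlation** between two measurement methods as a
   stand-in for the within-study correlation of their effect estimates:
   `cov = rho * se_a * se_b` (`approx_cov_from_patient_corr()`).
3. **Imputation/sensitivity**: a global assumed correlation for unstated
   pairs (`impute_rho`), swept over a grid by
   `sensitivity_within_corr()`. Unstated pairs default to covariance 0 with
   a one-off warning.

The continuity correction adds `1/(size of the opposite group)` to each
cell whenever a table contains a zero cell (and only then), keeping all log
odds ratios finite; a group with no subjects at all is an error.

## Numerical choices

* Optimiser: `nlminb` (quasi-Newton with numerical gradients) from three
  dispersed starts — a moment-flavoured start, a near-zero start, and an
  inflated start — with relative tolerance 1e-10; the best converged point
  wins.
* Unstructured `Omega` via log-Cholesky; log standard deviations bounded in
  [-15, 5], so variances can reach ~1e-13, i.e. effectively 0, and
  between-study correlations can approach ±1. Boundary correlations (a
  common occurrence: the packaged cut-point example fits at +1) are
  reported via the `boundary` diagnostic, not treated as errors.
* The restricted log-likelihood includes the `+ 0.5 log|X'X|` term, making
  it invariant to linear reparameterisation of the mean design and directly
  comparable with other mixed-model software.
* Univariate REML additionally checks the `tau^2 = 0` boundary explicitly
  and snaps estimates below 1e-10 to 0.
* Confidence intervals use normal quantiles; prediction intervals use *t*
  with df = (total studies in the analysis) − 2. The *t* convention
  back-calculates exactly against the published intervals the acceptance
  suite checks.
* Within-study correlations within 1e-9 of ±1 are clipped toward the
  interior so assembled `S_i` stay positive semi-definite; assembled blocks
  are eigenvalue-checked and a non-PSD `S_i` is an error naming the study.
* Mixed effect scales (log odds and log hazard ratios) in one dataset are
  refused rather than silently pooled.

## What the simulators emulate — and what they do not

`simulate_effects()` draws directly from the two-level normal hierarchy the
models assume: latent study effects from `N(beta, Omega)` (or from the
trend model when `beta` is set to `alpha + gamma f(x)` and `Omega` to
`tau_alpha^2 * J`), standard errors log-uniform over a user range
(mimicking the order-of-magnitude spread seen in real tables), and a common
within-study correlation. `simulate_cohorts()` generates subjects with a
normal factor and a logistic-linear outcome model, then tabulates 2x2
tables at the requested cut-points — exercising the reconstruction and
bootstrap machinery end to end. `apply_missingness()` thins records
completely at random, by level, or selectively by statistical significance
(the classic selective-reporting mechanism: significant results always
survive).

Passing parameter-recovery and borrowing-of-strength tests on these data
shows the estimators are correct *under the assumed model*. Real data
deviate in ways the generators deliberately do not emulate: standard errors
correlated with effect sizes (small-study effects), non-normal latent
effects, cut-points chosen post hoc to optimise p-values, bounded discrete
scores rather than a normal factor, and survival outcomes with censoring.
One concrete illustration: under the logistic-normal cohort model the true
log odds ratio is *not* monotone in the cut-point (it rises again in the
tails, where the comparison group becomes extreme), so a decreasing
odds-ratio pattern across cut-points is a property of particular score
distributions, not of dichotomisation per se.

## Problem sizes used by the test suite

The simulation-based checks run at sizes chosen to balance Monte-Carlo
resolution against desk-scale runtime: trend-parameter recovery uses 200
replicates of k = 40 studies over 6 cut-points; the borrowing-of-strength
and selective-reporting comparisons use 500 replicates of k = 12–14
two-level studies. Recovery is asserted within two Monte-Carlo standard
errors of the truth; the missing-data comparisons assert the joint model's
mean squared error does not exceed the univariate one (missing at random)
and that its bias is significantly smaller (selective reporting).

## Known limitations

* Restricted cubic splines and two-term fractional polynomials are not
  implemented; one-term fractional polynomials cover the published use.
* The reparameterised "overall correlation" model and robust-variance
  meta-regression for unknown correlations are out of scope.
* Method-of-moments multivariate estimators are not provided; REML only
  (the univariate module offers DerSimonian–Laird).
* Bootstrap reconstruction applies to unadjusted odds ratios from 2x2
  tables; adjusted effects or survival outcomes need the original
  participant data, which the package does not ingest.
* Between-study correlations estimated at the ±1 boundary are reported,
  not penalised; with few studies the between-study covariance is weakly
  identified, and prediction intervals should be read accordingly.
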