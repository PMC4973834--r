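Package: cutmeta
Title: Multivariate Meta-Analysis of Prognostic Factors at Multiple
    Cut-Points and Measurement Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesising prognostic factor studies that report
    effect estimates (log odds ratios or log hazard ratios) at several
    cut-points of a continuous factor and/or under several methods of
    measurement. Provides univariate random-effects meta-analysis with
    heterogeneity statistics and t-based prediction intervals, multivariate
    random-effects meta-analysis by restricted maximum likelihood with
    study-specific within-study covariance and unstructured or structured
    between-study covariance, trend models relating the summary effect to
    the cut-point through linear or fractional-polynomial functions,
    non-parametric bootstrap estimation of within-study correlations from
    reconstructed participant-level data, and simulation utilities for
    parameter-recovery and missing-data experiments. All fitting functions
    take tidy data frames and return objects with tidy(), glance() and
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
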