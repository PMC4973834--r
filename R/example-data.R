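#' Packaged example datasets
#'
#' Two published sets of study-level prognostic effect estimates, shipped
#' as plain CSV under `inst/extdata` and returned as ready-made
#' [meta_dataset] objects.
#'
#' `apgar_cutpoints()`: unadjusted log odds ratios of neonatal mortality
#' for a low (at or below the cut-point) versus higher Apgar score, from 10
#' studies of low-birth-weight babies. Five studies report both cut-points
#' 3 and 6 (with bootstrap-derived within-study correlations around +0.5),
#' four report only cut-point 3 and one only cut-point 6.
#'
#' `microvessel_density()`: adjusted log hazard ratios of mortality per
#' 1-unit increase in microvessel density in non-small-cell lung carcinoma,
#' measured by the Chalkley method and/or by counting all microvessels, in
#' 16 studies. Three studies used both methods; their patient-level
#' correlations between the methods (0.55, 0.74, 0.27) serve as
#' approximate within-study correlations.
#'
#' @return A [meta_dataset].
#' @name example_data
NULL

#' @rdname example_data
#' @export
apgar_cutpoints <- function() {
  read_effect_table(
    system.file("extdata", "apgar_cutpoints.csv", package = "cutmeta", mustWork = TRUE),
    system.file("extdata", "apgar_within_corr.csv", package = "cutmeta", mustWork = TRUE),
    scale = "log_odds"
  )
}

#' @rdname example_data
#' @export
microvessel_density <- function() {
  read_effect_table(
    system.file("extdata", "microvessel_density.csv", package = "cutmeta", mustWork = TRUE),
    system.file("extdata", "microvessel_within_corr.csv", package = "cutmeta", mustWork = TRUE),
    scale = "log_hazard"
  )
}
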