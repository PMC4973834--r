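#' Assemble a validated meta-analysis dataset
#'
#' Bundles study-level effect estimates, optional within-study correlations
#' and a level registry (the ordered set of cut-points and/or measurement
#' methods seen across studies) into a single validated object consumed by
#' all fitting functions.
#'
#' @param effects A data frame with one row per effect estimate. Required
#'   columns: `study_id`, `se`, and either `y` (the log odds/hazard ratio) or
#'   `effect_ratio` (the ratio itself, which is logged on import). At least
#'   one of `cutpoint` (numeric) or `method` (character) must be present to
#'   identify the level each estimate belongs to.
#' @param correlations Optional data frame with columns `study_id`,
#'   `level_a`, `level_b` and exactly one of `rho` (within-study correlation,
#'   in \[-1, 1\]) or `cov` (within-study covariance). An optional
#'   `provenance` column records how the value was obtained (`"bootstrap"`,
#'   `"patient_level_approx"` or `"imputed"`).
#' @param scale Effect scale, `"log_odds"` or `"log_hazard"`. Mixing scales
#'   within one analysis is refused.
#' @param flip_direction If `TRUE`, all estimates are negated on import.
#'   The stored convention is that estimates compare the odds (hazard) of
#'   the event for factor values at or below the cut-point against values
#'   above it; set this flag when the source used the opposite contrast.
#' @param impute_rho Optional correlation in (-1, 1) substituted for every
#'   within-study correlation that is not supplied. The default (`NULL`)
#'   uses 0 for unstated pairs, with a warning.
#'
#' @return An object of class `meta_dataset`: a list with tibbles
#'   `$effects` (with a derived `level` column), `$correlations` (with both
#'   `rho` and `cov` filled in), and `$levels` (the registry, ordered by
#'   method then cut-point), plus the scale.
#' @export
#' @examples
#' eff <- tibble::tibble(
#'   study_id = c("s1", "s1", "s2"), cutpoint = c(3, 6, 3),
#'   y = c(2.6, 2.4, 2.0), se = c(0.14, 0.15, 0.2)
#' )
#' cors <- tibble::tibble(study_id = "s1", level_a = "3", level_b = "6", rho = 0.59)
#' meta_dataset(eff, cors)
meta_dataset <- function(effects, correlations = NULL,
                         scale = c("log_odds", "log_hazard"),
                         flip_direction = FALSE, impute_rho = NULL) {
  scale <- match.arg(scale)
  effects <- as_tibble(effects)
  if (nrow(effects) == 0L) abort("no records: the effect table is empty")
  if (!"study_id" %in% names(effects)) abort("missing required column 'study_id'")
  if (!"se" %in% names(effects)) abort("missing required column 'se'")
  if (!"y" %in% names(effects)) {
    if ("effect_ratio" %in% names(effects)) {
      if (any(effects$effect_ratio <= 0)) abort("effect_ratio must be positive to take logs")
      effects$y <- log(effects$effect_ratio)
    } else {
      abort("missing required column 'y' (or 'effect_ratio')")
    }
  }
  if (!"cutpoint" %in% names(effects)) effects$cutpoint <- NA_real_
  if (!"method" %in% names(effects)) effects$method <- NA_character_
  effects$study_id <- as.character(effects$study_id)
  effects$cutpoint <- as.numeric(effects$cutpoint)
  effects$method <- as.character(effects$method)
  if (all(is.na(effects$cutpoint)) && all(is.na(effects$method))) {
    abort("each record needs a 'cutpoint' and/or a 'method' to define its level")
  }
  if (any(!is.finite(effects$y))) abort("non-finite effect estimate 'y'")
  bad_se <- !is.finite(effects$se) | effects$se <= 0
  if (any(bad_se)) {
    abort(paste0("non-positive se for study ", effects$study_id[which(bad_se)[1]]))
  }
  if ("scale" %in% names(effects)) {
    if (length(unique(effects$scale)) > 1L) {
      abort("mixed effect scales (log_odds and log_hazard) in one dataset are not supported")
    }
    scale <- match.arg(unique(effects$scale), c("log_odds", "log_hazard"))
  }
  if (flip_direction) effects$y <- -effects$y

  effects$level <- derive_level(effects$cutpoint, effects$method)
  dup <- duplicated(effects[c("study_id", "level")])
  if (any(dup)) {
    abort(paste0(
      "duplicate (study, level) pair: study ", effects$study_id[which(dup)[1]],
      ", level ", effects$level[which(dup)[1]]
    ))
  }
  registry <- level_registry(effects)
  effects <- dplyr::arrange(
    effects,
    .data$study_id, match(.data$level, registry$level)
  )
  effects <- effects[c("study_id", "level", "cutpoint", "method", "y", "se")]

  correlations <- validate_correlations(correlations, effects)

  structure(
    list(
      effects = effects, correlations = correlations, levels = registry,
      scale = scale, impute_rho = impute_rho
    ),
    class = "meta_dataset"
  )
}

# level labels: cut-point value, method label, or "method:cutpoint"
derive_level <- function(cutpoint, method) {
  has_cut <- !is.na(cutpoint)
  has_meth <- !is.na(method) & method != ""
  dplyr::case_when(
    has_cut & has_meth ~ paste(method, format_num(cutpoint), sep = ":"),
    has_cut ~ format_num(cutpoint),
    has_meth ~ method,
    TRUE ~ NA_character_
  )
}

format_num <- function(x) {
  vapply(x, function(v) if (is.na(v)) NA_character_ else format(v, digits = 15, trim = TRUE),
    character(1)
  )
}

level_registry <- function(effects) {
  reg <- dplyr::distinct(effects, .data$level, .data$cutpoint, .data$method)
  if (anyDuplicated(reg$level)) {
    abort("a level label maps to more than one (cutpoint, method) definition")
  }
  reg <- dplyr::arrange(reg, .data$method, .data$cutpoint)
  cuts <- reg$cutpoint[!is.na(reg$cutpoint)]
  if (length(unique(reg$method[!is.na(reg$method)])) <= 1L &&
    is.unsorted(cuts, strictly = TRUE) && length(cuts) > 1L) {
    abort("cut-points must be strictly increasing in the level registry")
  }
  reg
}

validate_correlations <- function(correlations, effects) {
  empty <- tibble(
    study_id = character(), level_a = character(), level_b = character(),
    rho = double(), cov = double(), provenance = character()
  )
  if (is.null(correlations) || nrow(correlations) == 0L) return(empty)
  correlations <- as_tibble(correlations)
  need <- c("study_id", "level_a", "level_b")
  miss <- setdiff(need, names(correlations))
  if (length(miss)) abort(paste0("correlation table missing column '", miss[1], "'"))
  if (!"rho" %in% names(correlations)) correlations$rho <- NA_real_
  if (!"cov" %in% names(correlations)) correlations$cov <- NA_real_
  if (!"provenance" %in% names(correlations)) correlations$provenance <- NA_character_
  correlations$study_id <- as.character(correlations$study_id)
  correlations$level_a <- as.character(correlations$level_a)
  correlations$level_b <- as.character(correlations$level_b)

  both <- !is.na(correlations$rho) & !is.na(correlations$cov)
  neither <- is.na(correlations$rho) & is.na(correlations$cov)
  if (any(neither)) abort("each correlation row needs rho or cov")

  key <- function(s, a, b) paste(s, a, b, sep = "\r")
  se_of <- setNames(effects$se, key(effects$study_id, effects$level, effects$level))
  lookup_se <- function(s, l) {
    i <- which(effects$study_id == s & effects$level == l)
    if (length(i) != 1L) {
      abort(paste0("correlation row refers to unknown record: study ", s, ", level ", l))
    }
    effects$se[i]
  }
  for (r in seq_len(nrow(correlations))) {
    se_a <- lookup_se(correlations$study_id[r], correlations$level_a[r])
    se_b <- lookup_se(correlations$study_id[r], correlations$level_b[r])
    if (both[r]) {
      # both stated: accept only if mutually consistent (supports round trips)
      if (abs(correlations$cov[r] - correlations$rho[r] * se_a * se_b) >
        1e-8 * max(1, abs(correlations$cov[r]))) {
        abort(paste0(
          "rho and cov disagree for study ", correlations$study_id[r],
          " (cov must equal rho * se_a * se_b); supply one of the two"
        ))
      }
    } else if (is.na(correlations$rho[r])) {
      correlations$rho[r] <- correlations$cov[r] / (se_a * se_b)
    } else {
      correlations$cov[r] <- correlations$rho[r] * se_a * se_b
    }
  }
  bad <- abs(correlations$rho) > 1
  if (any(bad)) {
    r <- which(bad)[1]
    abort(paste0(
      "|rho| > 1 for study ", correlations$study_id[r], ", levels ",
      correlations$level_a[r], "/", correlations$level_b[r],
      " (rho = ", signif(correlations$rho[r], 4), ")"
    ))
  }
  # clip correlations within 1e-9 of +/-1 toward the interior so the
  # within-study covariance matrix stays positive semi-definite
  near <- abs(correlations$rho) > 1 - 1e-9
  if (any(near)) {
    shrink <- sign(correlations$rho[near]) * (1 - 1e-9)
    correlations$cov[near] <- correlations$cov[near] * shrink / correlations$rho[near]
    correlations$rho[near] <- shrink
  }
  dup <- duplicated(rbind(
    correlations[c("study_id", "level_a", "level_b")],
    setNames(
      correlations[c("study_id", "level_b", "level_a")],
      c("study_id", "level_a", "level_b")
    )
  ))[seq_len(nrow(correlations))]
  if (any(dup)) abort("duplicate correlation row for the same study and level pair")
  correlations
}

#' Read a long-format effect table (and optional correlation table) from CSV
#'
#' @param path Path to a delimited file with columns `study_id`, `se`,
#'   `y` or `effect_ratio`, and `cutpoint` and/or `method`.
#' @param corr_path Optional path to a correlation CSV with columns
#'   `study_id`, `level_a`, `level_b` and `rho` or `cov`.
#' @inheritParams meta_dataset
#' @return A [meta_dataset].
#' @export
read_effect_table <- function(path, corr_path = NULL,
                              scale = c("log_odds", "log_hazard"),
                              flip_direction = FALSE, impute_rho = NULL) {
  effects <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(effects) == 0L) abort("no records: the effect table is empty")
  correlations <- NULL
  if (!is.null(corr_path)) {
    correlations <- readr::read_csv(corr_path, show_col_types = FALSE, progress = FALSE)
  }
  meta_dataset(effects, correlations,
    scale = scale,
    flip_direction = flip_direction, impute_rho = impute_rho
  )
}

#' Write a meta-analysis dataset back to CSV
#'
#' Writes the effect table and (when non-empty) the correlation table with
#' full precision, so that reading them back reproduces the dataset.
#'
#' @param dataset A [meta_dataset].
#' @param path Path for the effect CSV.
#' @param corr_path Optional path for the correlation CSV.
#' @return `dataset`, invisibly.
#' @export
write_meta_dataset <- function(dataset, path, corr_path = NULL) {
  stopifnot(inherits(dataset, "meta_dataset"))
  readr::write_csv(dataset$effects, path, progress = FALSE)
  if (!is.null(corr_path) && nrow(dataset$correlations) > 0L) {
    readr::write_csv(dataset$correlations, corr_path, progress = FALSE)
  }
  invisible(dataset)
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(
    "<meta_dataset> ", dplyr::n_distinct(x$effects$study_id), " studies, ",
    nrow(x$effects), " estimates across ", nrow(x$levels), " level(s) [",
    x$scale, "]\n",
    sep = ""
  )
  print(x$levels)
  invisible(x)
}

#' Build per-study blocks (effect vector + within-study covariance matrix)
#'
#' Each study contributes the sub-vector of estimates for the levels it
#' reports, together with its within-study covariance matrix: diagonal
#' entries are `se^2`, off-diagonal entries come from the correlation table
#' (`cov = rho * se_a * se_b`). Pairs without a stated covariance use the
#' dataset's `impute_rho` if set, otherwise 0 (with a one-off warning).
#'
#' @param dataset A [meta_dataset].
#' @param impute_rho Optional override of the dataset's imputed correlation.
#' @return A list of blocks, one per study, each a list with `study_id`,
#'   `levels` (character), `idx` (positions in the level registry), `y` and
#'   `S`. The list carries the registry as attribute `"levels"`.
#' @export
assemble_blocks <- function(dataset, impute_rho = NULL) {
  stopifnot(inherits(dataset, "meta_dataset"))
  impute_rho <- impute_rho %||% dataset$impute_rho
  if (!is.null(impute_rho) && abs(impute_rho) >= 1) {
    abort("impute_rho must lie strictly inside (-1, 1)")
  }
  eff <- dataset$effects
  cors <- dataset$correlations
  registry <- dataset$levels
  warned <- FALSE

  blocks <- lapply(split(eff, eff$study_id), function(s) {
    ord <- order(match(s$level, registry$level))
    s <- s[ord, ]
    d <- nrow(s)
    S <- diag(s$se^2, nrow = d)
    dimnames(S) <- list(s$level, s$level)
    if (d > 1L) {
      for (a in seq_len(d - 1L)) {
        for (b in seq((a + 1L), d)) {
          hit <- cors$study_id == s$study_id[1] &
            ((cors$level_a == s$level[a] & cors$level_b == s$level[b]) |
              (cors$level_a == s$level[b] & cors$level_b == s$level[a]))
          if (any(hit)) {
            S[a, b] <- S[b, a] <- cors$cov[which(hit)[1]]
          } else if (!is.null(impute_rho)) {
            S[a, b] <- S[b, a] <- impute_rho * s$se[a] * s$se[b]
          } else {
            if (!warned) {
              warn("unstated within-study covariances set to 0 (set impute_rho to change this)")
              warned <<- TRUE
            }
          }
        }
      }
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev))) {
        abort(paste0(
          "within-study covariance matrix of study ", s$study_id[1],
          " is not positive semi-definite"
        ))
      }
    }
    list(
      study_id = s$study_id[1], levels = s$level,
      idx = match(s$level, registry$level),
      y = setNames(s$y, s$level), S = S
    )
  })
  blocks <- unname(blocks)
  attr(blocks, "levels") <- registry
  attr(blocks, "scale") <- dataset$scale
  blocks
}

#' Within-study covariance from a patient-level correlation
#'
#' When two measurement methods are recorded on the same patients, the
#' patient-level correlation between the methods can stand in for the
#' within-study correlation of their effect estimates; the implied
#' covariance is `rho * se_a * se_b`.
#'
#' @param rho_patient Patient-level correlation, in \[-1, 1\].
#' @param se_a,se_b Standard errors of the two effect estimates.
#' @return The approximated within-study covariance.
#' @export
#' @examples
#' approx_cov_from_patient_corr(0.55, 0.065, 0.091)
approx_cov_from_patient_corr <- function(rho_patient, se_a, se_b) {
  if (any(!is.finite(rho_patient)) || any(abs(rho_patient) > 1)) {
    abort("|rho_patient| must be <= 1")
  }
  if (any(se_a <= 0) || any(se_b <= 0)) abort("standard errors must be positive")
  rho_patient * se_a * se_b
}
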