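# ggplot2 graphics for fitted objects

#' Plot study estimates and fitted cut-point trends
#'
#' Draws the per-study log effect estimates against the cut-point and
#' overlays the summary curve of each supplied trend fit, evaluated on a
#' grid over the observed cut-point range.
#'
#' @param data A [meta_dataset] whose levels carry cut-points.
#' @param fits A single `meta_trend` fit or a (optionally named) list of
#'   them; `NULL` draws the study estimates only.
#' @param exponentiate Plot odds/hazard ratios on a log-scaled axis rather
#'   than log effects.
#' @param n_grid Grid size for the fitted curves.
#' @return A ggplot object.
#' @export
plot_trend <- function(data, fits = NULL, exponentiate = FALSE, n_grid = 100) {
  stopifnot(inherits(data, "meta_dataset"))
  eff <- data$effects
  if (all(is.na(eff$cutpoint))) abort("the dataset has no cut-points to plot")
  if (inherits(fits, "meta_trend")) fits <- list(fits)
  if (dplyr::n_distinct(eff$study_id) < 2L && length(fits)) {
    warn("only one study: drawing its estimates without a summary curve")
    fits <- NULL
  }
  pts <- eff
  trans <- if (exponentiate) exp else identity
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$cutpoint, y = trans(.data$y))) +
    ggplot2::geom_point(ggplot2::aes(group = .data$study_id), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(group = .data$study_id),
      alpha = 0.25, linewidth = 0.3
    ) +
    ggplot2::labs(
      x = "Cut-point",
      y = if (exponentiate) {
        if (data$scale == "log_hazard") "Hazard ratio" else "Odds ratio"
      } else {
        if (data$scale == "log_hazard") "Log hazard ratio" else "Log odds ratio"
      }
    ) +
    ggplot2::theme_minimal()
  if (exponentiate) p <- p + ggplot2::scale_y_log10()
  if (length(fits)) {
    nm <- names(fits) %||% vapply(fits, function(f) {
      if (f$transform$family == "linear") "linear" else paste0("FP(", f$transform$power, ")")
    }, character(1))
    curves <- purrr::map_dfr(seq_along(fits), function(i) {
      f <- fits[[i]]
      xg <- seq(f$x_range[1], f$x_range[2], length.out = n_grid)
      pr <- predict_cutpoint(f, xg)
      tibble(x = xg, y = trans(pr$estimate), model = nm[i])
    })
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$model),
      linewidth = 0.9, inherit.aes = FALSE
    ) +
      ggplot2::labs(colour = "Trend")
  }
  p
}

#' @export
autoplot.meta_trend <- function(object, data = NULL, ...) {
  pts <- object$points
  if (is.null(pts) && inherits(data, "meta_dataset")) pts <- data$effects
  if (is.null(pts)) abort("no study estimates stored; pass the dataset via `data = `")
  ds <- base::structure(
    list(
      effects = pts, scale = object$scale,
      levels = object$levels
    ),
    class = "meta_dataset"
  )
  plot_trend(ds, fits = list(object), ...)
}

#' @export
autoplot.meta_mv <- function(object, exponentiate = TRUE, coverage = 0.95, ...) {
  td <- tidy(object)
  pis <- purrr::map_dfr(
    td$level,
    function(l) prediction_interval(object, level = l, coverage = coverage)
  )
  df <- dplyr::left_join(td, pis, by = "level")
  trans <- if (exponentiate) exp else identity
  ggplot2::ggplot(df, ggplot2::aes(y = .data$level)) +
    ggplot2::geom_linerange(
      ggplot2::aes(xmin = trans(.data$lo), xmax = trans(.data$hi)),
      linewidth = 0.4, colour = "grey50"
    ) +
    ggplot2::geom_pointrange(ggplot2::aes(
      x = trans(.data$estimate),
      xmin = trans(.data$conf.low), xmax = trans(.data$conf.high)
    )) +
    ggplot2::geom_vline(xintercept = trans(0), linetype = 2) +
    ggplot2::labs(
      x = if (exponentiate) {
        if (object$scale == "log_hazard") "Hazard ratio" else "Odds ratio"
      } else {
        "Log effect"
      },
      y = "Level",
      caption = "thick: 95% CI; thin: prediction interval"
    ) +
    ggplot2::theme_minimal() +
    if (exponentiate) ggplot2::scale_x_log10() else NULL
}
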