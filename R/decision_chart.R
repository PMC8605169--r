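# Sigma zone labels, best performance first. Bands are closed on their
# lower edge: a sigma exactly on a boundary belongs to the upper band.
SIGMA_ZONES <- c("sigma>=6", "6>sigma>=5", "5>sigma>=4",
                 "4>sigma>=3", "3>sigma>=2", "sigma<2")

#' Sigma zone of a sigma value
#'
#' Assigns the six performance zones used on normalized method decision
#' charts: `sigma>=6`, `6>sigma>=5`, `5>sigma>=4`, `4>sigma>=3`,
#' `3>sigma>=2`, `sigma<2`. Bands are closed on the lower edge, so
#' `band(5) == "6>sigma>=5"` and `band(6) == "sigma>=6"`. Infinite sigma
#' (zero CV) maps to the top zone, negative sigma to the bottom one.
#'
#' @param sigma Numeric vector of sigma values.
#' @return Factor with the six zone labels as levels (best first).
#' @export
sigma_band <- function(sigma) {
  # snap values a rounding error away from a boundary onto it, so points
  # constructed exactly on a zone line classify into the lower-edge band
  near <- is.finite(sigma) & round(sigma) %in% 2:6 &
    abs(sigma - round(sigma)) < 1e-9
  sigma[near] <- round(sigma[near])
  # cut()'s outer intervals are open at +/-Inf; map the sentinels inside
  sigma[is.infinite(sigma)] <- sign(sigma[is.infinite(sigma)]) *
    .Machine$double.xmax
  cut(sigma, breaks = c(-Inf, 2, 3, 4, 5, 6, Inf),
      labels = rev(SIGMA_ZONES), right = FALSE) |>
    factor(levels = SIGMA_ZONES)
}

#' Normalize performance records onto decision-chart coordinates
#'
#' On a normalized method decision chart the x-axis is `100 * CV / TEa` and
#' the y-axis is `100 * bias / TEa`, so every analyte shares one plot
#' regardless of its goal. The line for sigma level `s` is `y = 100 - s x`
#' (all lines meet at (0, 100)); the five lines for s = 2..6 cut the plane
#' into the six sigma zones.
#'
#' @param records Tibble with columns `lab`, `analyte`, `level`, `cv`,
#'   `bias`, `tea` (e.g. from [performance_table()]).
#' @return Tibble with `lab`, `analyte`, `level`, `x`, `y`, `zone`.
#' @export
normalize_points <- function(records) {
  if (any(records$tea <= 0)) stop("TEa must be positive", call. = FALSE)
  if (any(records$cv <= 0)) {
    stop("CV must be positive to place a point on the chart", call. = FALSE)
  }
  tibble::tibble(
    lab = records$lab,
    analyte = records$analyte,
    level = records$level,
    x = 100 * records$cv / records$tea,
    y = 100 * abs(records$bias) / records$tea,
    zone = sigma_band((100 - 100 * abs(records$bias) / records$tea) /
                        (100 * records$cv / records$tea))
  )
}

#' Render a normalized method decision chart
#'
#' Draws the five sigma boundary lines (`y = 100 - s x`, s = 2..6) on a
#' fixed 0-100% frame, one labeled point per assay, colored by laboratory.
#' Points beyond the frame are clamped to the margin and drawn with an
#' out-of-range marker (cross). Output is an SVG whose bytes depend only on
#' the input (no timestamps), so charts are diffable.
#'
#' @param points Tibble from [normalize_points()], already filtered to one
#'   control level.
#' @param level The control-level tag the points share (checked).
#' @param out_path Output `.svg` path.
#' @param title Optional chart title; defaults to the level tag.
#' @return `out_path`, invisibly.
#' @export
render_chart <- function(points, level, out_path, title = NULL) {
  if (nrow(points) && !all(points$level == level)) {
    stop("all points must share level '", level, "'", call. = FALSE)
  }
  slopes <- tibble::tibble(s = 2:6)
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(
      data = slopes,
      mapping = ggplot2::aes(slope = -.data$s, intercept = 100),
      linewidth = 0.4, colour = "grey40"
    ) +
    ggplot2::annotate(
      "text",
      x = c(10, 14, 19, 26, 40, 75),
      y = c(3, 35, 45, 55, 65, 75),
      label = SIGMA_ZONES, size = 3, colour = "grey30"
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100),
                             expand = FALSE) +
    ggplot2::labs(
      title = title %||% paste("Normalized method decision chart —", level),
      x = "CV / TEa (%)  [imprecision]",
      y = "Bias / TEa (%)  [trueness]",
      colour = "Laboratory"
    ) +
    ggplot2::theme_bw()
  if (nrow(points)) {
    pts <- points |>
      dplyr::mutate(
        out_of_range = .data$x > 100 | .data$y > 100,
        x_plot = pmin(.data$x, 100),
        y_plot = pmin(.data$y, 100)
      ) |>
      dplyr::arrange(.data$lab, .data$analyte)
    p <- p +
      ggplot2::geom_point(
        data = pts,
        mapping = ggplot2::aes(x = .data$x_plot, y = .data$y_plot,
                               colour = .data$lab,
                               shape = .data$out_of_range),
        size = 2
      ) +
      ggplot2::geom_text(
        data = pts,
        mapping = ggplot2::aes(x = .data$x_plot, y = .data$y_plot,
                               label = .data$analyte),
        size = 2.4, vjust = -0.9, check_overlap = FALSE
      ) +
      ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                  guide = "none")
  }
  grDevices::svg(out_path, width = 7, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(out_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
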