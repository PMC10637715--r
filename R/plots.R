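#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_long <- function(values, resolution, origin) {
  h <- nrow(values); w <- ncol(values)
  tibble::tibble(
    x = rep(origin[1] + (seq_len(w) - 0.5) * resolution, each = h),
    y = rep(origin[2] - (seq_len(h) - 0.5) * resolution, times = w),
    value = as.vector(values)
  )
}

#' Plot an index raster
#'
#' @param object An `index_raster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot index_raster
#' @export
autoplot.index_raster <- function(object, ...) {
  df <- raster_long(object$values, object$resolution, object$origin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#e6b800", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey80",
                                  name = toupper(object$index)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot an elevation raster
#'
#' @param object An `elevation_raster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot elevation_raster
#' @export
autoplot.elevation_raster <- function(object, ...) {
  df <- raster_long(object$values, object$resolution, object$origin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80",
                                  name = sprintf("%s (m)", object$kind)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a semantic class map
#'
#' @param object A `class_map`.
#' @param ... Unused.
#' @return A ggplot object with field-style colours: brown soil, green
#'   vegetation, yellow flowers.
#' @method autoplot class_map
#' @export
autoplot.class_map <- function(object, ...) {
  df <- raster_long(object$labels, object$resolution, object$origin)
  df$class <- factor(object$class_levels[df$value], levels = object$class_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(soil = "#8c6d4f", vegetation = "#2e7d32",
                 flower = "#f2c200", unclassified = "grey65"),
      na.value = "grey90", drop = FALSE, name = "class") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot estimated against actual yields
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot scatter with the 1:1 line and the least-squares fit.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimated, y = .data$actual)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#b2182b") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "estimated yield (t/ha)", y = "actual yield (t/ha)",
                  subtitle = sprintf("R² = %.3f, RMSE = %.3f t/ha",
                                     object$r2, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Plot a growth-stage height series
#'
#' @param series A [stage_series()] tibble.
#' @return A ggplot of min/mean/max canopy height by stage.
#' @export
plot_stage_series <- function(series) {
  df <- series
  df$stage <- factor(df$stage, levels = OSR_STAGES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "#2e7d32", alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "#2e7d32") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean, shape = .data$is_max_mean),
                        size = 3, colour = "#2e7d32") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "max mean height") +
    ggplot2::labs(x = "growth stage", y = "canopy height (m)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
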