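#' Plot a proxy series
#'
#' @param object A `proxy_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.proxy_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "year AD", y = series_label(object)) +
    ggplot2::theme_minimal()
}

#' Plot a regime shift segmentation
#'
#' Series with thick horizontal lines at the Huber-weighted regime
#' means, the standard display of periods of similar mean conditions.
#'
#' @param object A `regime_shift` object from [detect_regimes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regime_shift <- function(object, ...) {
  reg <- tidy(object)
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "grey55", linewidth = 0.3) +
    ggplot2::geom_segment(
      data = reg,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean, yend = .data$mean),
      colour = "firebrick", linewidth = 1.2, inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "year AD", y = series_label(object$series)) +
    ggplot2::theme_minimal()
}

#' Plot per-year LFY diagnostics
#'
#' Burned fraction per year with flagged large fire years highlighted.
#'
#' @param object An `lfy_result` from [detect_lfy()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lfy_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year,
                                   y = .data$fraction_burned)) +
    ggplot2::geom_col(width = 0.8, fill = "grey60") +
    ggplot2::geom_point(data = df[df$is_lfy, ], colour = "firebrick",
                        size = 2) +
    ggplot2::labs(x = "year AD", y = "fraction of sites burned") +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap null distribution of the cold/warm test
#'
#' @param object An `lfy_regime_test` from [bootstrap_lfy_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lfy_regime_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_diff)) +
    ggplot2::geom_bar(fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_diff,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "cold - warm LFY count (null draws)", y = "draws") +
    ggplot2::theme_minimal()
}

#' Plot a correlation map
#'
#' Correlation coefficients as a lat/lon raster, with locally
#' significant cells outlined.
#'
#' @param object A `correlation_map` from [correlation_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$r)) +
    ggplot2::geom_point(data = df[which(df$significant), ],
                        shape = 4, size = 0.6, colour = "black") +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(
      x = "longitude", y = "latitude", fill = "r",
      subtitle = sprintf("%.0f%% of cells significant, p_field = %.3g",
                         100 * object$frac_significant, object$p_field)
    ) +
    ggplot2::theme_minimal()
}

#' Plot superposed epoch composites
#'
#' One anomaly map per analyzed month, significant cells outlined.
#'
#' @param object An `sea_result` from [sea()].
#' @param alpha Significance level used to mark cells.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sea_result <- function(object, alpha = 0.1, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$composite)) +
    ggplot2::geom_point(data = df[df$p <= alpha, ],
                        shape = 4, size = 0.6, colour = "black") +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "anomaly") +
    ggplot2::theme_minimal()
  if (length(object$months) > 1L) {
    p <- p + ggplot2::facet_wrap(~month)
  }
  p
}
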