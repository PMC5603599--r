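#' Plot a lag-correlation curve
#'
#' @param object A `lag_curve` from [cross_correlate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lag_curve <- function(object, ...) {
  peak <- select_peak(object)
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$lag_s, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = peak$lag_s, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "Lag (s; positive = autonomic lags cortical)",
      y = "Cross-correlation r",
      title = sprintf("%s vs %s: r = %.3f at %+d s",
                      attr(object, "x_label"), attr(object, "y_label"),
                      peak$r, as.integer(peak$lag_s))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fluctuation-period decomposition
#'
#' Shows the tent-filtered signal with its detected extrema; retained
#' maxima (those whose cycle amplitude exceeds the median) are
#' highlighted — the median period is measured between consecutive
#' retained maxima.
#'
#' @param object A `fluctuation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluctuation_result <- function(object, ...) {
  df <- tibble(time_s = seq_along(object$filtered) - 1,
               value = object$filtered)
  mx <- tibble(
    time_s = object$cycles$max_idx - 1,
    value = object$filtered[object$cycles$max_idx],
    retained = object$cycles$retained
  )
  mn <- tibble(time_s = object$minima_idx - 1,
               value = object$filtered[object$minima_idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = mn, shape = 1) +
    ggplot2::geom_point(data = mx, ggplot2::aes(colour = .data$retained)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(
      x = "Time (s)", y = "Filtered signal",
      title = sprintf("n_f = %g s: median period %.1f s (%d/%d cycles retained)",
                      object$width_s, object$median_period_s,
                      object$n_retained, object$n_cycles),
      colour = "Retained"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an averaged ERP waveform
#'
#' @param object An `erp_average`.
#' @param peaks Optional `erp_peaks` row to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.erp_average <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$time_ms, y = .data$amplitude_uv)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (ms)", y = "Amplitude (µV)",
      title = sprintf("ERP average%s (n = %d)",
                      if (is.null(object$condition)) ""
                      else paste0(" — ", object$condition),
                      object$n_epochs)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    ann <- tibble(
      time_ms = c(peaks$n1_lat_ms, peaks$p2_lat_ms),
      amplitude_uv = c(peaks$n1_amp_uv, peaks$p2_amp_uv),
      component = c("N1", "P2")
    )
    p <- p + ggplot2::geom_point(data = ann, colour = "firebrick") +
      ggplot2::geom_text(data = ann, ggplot2::aes(label = .data$component),
                         vjust = -1, colour = "firebrick")
  }
  p
}

#' Plot the filter-width scan
#'
#' p-values of the period-vs-C_max correlation as a function of tent
#' width, the diagnostic used to choose the analysis widths.
#'
#' @param scan Tibble from [scan_filter_widths()].
#' @param alpha Reference significance level drawn as a rule.
#' @return A ggplot object.
#' @export
plot_width_scan <- function(scan, alpha = 0.05) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$width_s, y = .data$p)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Tent-filter width n_f (s)",
                  y = "p (period vs C_max correlation)") +
    ggplot2::theme_minimal()
}
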