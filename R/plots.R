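#' Plot a power spectrum
#'
#' @param object a `power_spectrum`.
#' @param log_y log10-scale the density axis.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$frequency_hz, .data$psd)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz))) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot spike-triggered relative LFP power over frequency
#'
#' @param object a `coupling_result`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot coupling_result
#' @export
autoplot.coupling_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$frequency_hz, .data$st_rel_power)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Relative spike-triggered power") +
    ggplot2::theme_minimal()
}

#' Plot the repeated-CV accuracy distribution
#'
#' @param object a `knn_cv`.
#' @param ... unused.
#' @return A ggplot histogram with the median marked.
#' @method autoplot knn_cv
#' @export
autoplot.knn_cv <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = object$median_accuracy,
                        color = "firebrick", linewidth = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "Held-out accuracy", y = "Iterations") +
    ggplot2::theme_minimal()
}

#' Plot a classifier decision map
#'
#' Embedded animals over the nearest-neighbor class tessellation of the
#' embedded plane.
#'
#' @param object a `decision_map`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot decision_map
#' @export
autoplot.decision_map <- function(object, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_tile(data = object$grid,
                       ggplot2::aes(.data$dim1, .data$dim2,
                                    fill = .data$class), alpha = 0.3) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
  if ("label" %in% names(object$points)) {
    p + ggplot2::geom_point(data = object$points,
                            ggplot2::aes(.data$dim1, .data$dim2,
                                         color = .data$label), size = 2)
  } else {
    p + ggplot2::geom_point(data = object$points,
                            ggplot2::aes(.data$dim1, .data$dim2), size = 2)
  }
}

#' Plot a signal trace with detected oscillation intervals
#'
#' @param x numeric signal vector (uV).
#' @param fs sampling rate, Hz.
#' @param events event tibble from [detect_oscillations()].
#' @param max_s plot at most this many seconds.
#' @return A ggplot.
#' @export
plot_events <- function(x, fs, events, max_s = 60) {
  n <- min(length(x), round(max_s * fs))
  df <- tibble::tibble(t = (seq_len(n) - 1) / fs, x = x[seq_len(n)])
  ev <- events[events$start_s < max_s, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$x)) +
    ggplot2::geom_rect(
      data = ev, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$stop_s,
                   ymin = -Inf, ymax = Inf),
      fill = "goldenrod", alpha = 0.3) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = expression(LFP ~ (mu * V))) +
    ggplot2::theme_minimal()
}
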