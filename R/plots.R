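# ggplot2 graphics for the package's result types.

#' Raster plot of spike data
#'
#' @param spikes Spike data.
#' @param color_by `"population"` or `NULL`.
#' @return A ggplot object.
#' @export
plot_raster <- function(spikes, color_by = "population") {
  aes <- if (!is.null(color_by) && color_by %in% names(spikes)) {
    ggplot2::aes(x = .data$time, y = .data$neuron,
                 color = .data[[color_by]])
  } else {
    ggplot2::aes(x = .data$time, y = .data$neuron)
  }
  ggplot2::ggplot(spikes, aes) +
    ggplot2::geom_point(shape = ".", alpha = 0.8) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' State-space map of pulse-packet propagation
#'
#' @param samples Tibble (`sigma`, `a`, `success`).
#' @param fit Optional [fit_separatrix()] result whose 50% contour is drawn.
#' @return A ggplot object.
#' @export
plot_state_space <- function(samples, fit = NULL) {
  p <- ggplot2::ggplot(samples,
                       ggplot2::aes(x = .data$sigma, y = .data$a,
                                    color = .data$success)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(sigma[0] ~ "(ms)"), y = expression(a[0])) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    sg <- seq(fit$sigma_range[1], fit$sigma_range[2], length.out = 100)
    line <- tibble::tibble(sigma = sg, a = fit$boundary(sg))
    p <- p + ggplot2::geom_line(data = line, ggplot2::aes(x = .data$sigma,
                                                          y = .data$a),
                                inherit.aes = FALSE, color = "darkgreen")
  }
  p
}

#' @export
autoplot.separatrix_fit <- function(object, ...) {
  plot_state_space(object$samples, object)
}

#' @export
autoplot.rate_spectrum <- function(object, ...) {
  peak <- attr(object, "peak_freq")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$freq)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$power_raw), color = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$power), color = "steelblue") +
    ggplot2::labs(x = "frequency (Hz)", y = "power") +
    ggplot2::theme_minimal()
  if (!is.na(peak)) p <- p + ggplot2::geom_vline(xintercept = peak,
                                                 linetype = "dashed")
  p
}

#' @export
autoplot.gain_function <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rate_in,
                                       y = .data$rate_out)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$rate_out - .data$stderr,
      ymax = .data$rate_out + .data$stderr)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "afferent rate (Hz)", y = "output rate (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.iterative_compensation <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_hline(yintercept = object$nu_target, linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rate)) +
    ggplot2::labs(x = "iteration", y = "mean rate (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.attractor_episodes <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                                    ymin = .data$pattern - 0.4,
                                    ymax = .data$pattern + 0.4),
                       fill = "steelblue") +
    ggplot2::labs(x = "time (ms)", y = "pattern") +
    ggplot2::theme_minimal()
}
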