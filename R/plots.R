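# ggplot2 views of the main result types.

#' Plot a depth imagelet
#'
#' @param imagelet Depth matrix (mm).
#' @param background_mm Background depth for the color scale ceiling.
#' @param theta Optional orientation(s) (radians) drawn as bars through the
#'   center (e.g. ground truth and prediction).
#' @return A ggplot.
#' @export
plot_imagelet <- function(imagelet, background_mm = max(imagelet),
                          theta = NULL) {
  S <- nrow(imagelet)
  df <- tidyr::expand_grid(row = seq_len(S), col = seq_len(S))
  df$depth <- as.numeric(imagelet[cbind(df$row, df$col)])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = S + 1 - .data$row,
                                        fill = .data$depth)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "grey90",
                                 limits = c(NA, background_mm)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "depth (mm)")
  if (!is.null(theta)) {
    c0 <- (S + 1) / 2
    L <- S / 2.2
    seg <- tibble::tibble(theta = theta,
                          x = c0 - L * sin(theta), xend = c0 + L * sin(theta),
                          y = c0 + L * cos(theta), yend = c0 - L * cos(theta),
                          which = factor(seq_along(theta)))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, color = .data$which),
      inherit.aes = FALSE, linewidth = 1) +
      ggplot2::labs(color = "orientation")
  }
  p
}

#' @rdname autoplot-pedorient
#' @export
autoplot.orientation_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_s,
                                       y = .data$theta * 180 / pi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "orientation (deg, unwrapped)")
}

#' Autoplot methods for pedorient result objects
#'
#' @param object A result object (`orientation_signal`, `learning_curve`,
#'   `delay_estimate`, `model_comparison`).
#' @param which For `model_comparison`: `"difference"`, `"delay"` or `"psd"`.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-pedorient
#' @export
autoplot.learning_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$summary,
    cols = c("armse_gt_deg", "armse_noisy_deg", "aggregate_bias_deg"),
    names_to = "metric", values_to = "deg")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$N, y = .data$deg,
                                     color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "training-set size N", y = "error (deg)")
}

#' @rdname autoplot-pedorient
#' @export
autoplot.delay_estimate <- function(object, ...) {
  ggplot2::ggplot(object$windows, ggplot2::aes(x = .data$delay_s)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30) +
    ggplot2::geom_vline(xintercept = object$mean_s, color = "red") +
    ggplot2::labs(x = "delay (s)", y = "pdf")
}

#' @rdname autoplot-pedorient
#' @export
autoplot.model_comparison <- function(object,
                                      which = c("difference", "delay", "psd"),
                                      ...) {
  which <- match.arg(which)
  if (which == "difference") {
    df <- tibble::tibble(diff_deg = object$differences * 180 / pi)
    mu <- object$diff_fit$mean * 180 / pi
    sd <- object$diff_fit$sd * 180 / pi
    ggplot2::ggplot(df, ggplot2::aes(x = .data$diff_deg)) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                              bins = 60) +
      ggplot2::stat_function(fun = stats::dnorm,
                             args = list(mean = mu, sd = sd), color = "red") +
      ggplot2::labs(x = "shifted difference (deg)", y = "pdf")
  } else if (which == "delay") {
    df <- tibble::tibble(delay_s = object$delays)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$delay_s)) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                              bins = 40) +
      ggplot2::geom_vline(xintercept = object$params$d_hat, color = "red") +
      ggplot2::labs(x = "delay (s)", y = "pdf")
  } else {
    long <- tidyr::pivot_longer(object$psd,
                                cols = c("psd_theta", "psd_theta_v_norm"),
                                names_to = "signal", values_to = "psd")
    ggplot2::ggplot(dplyr::filter(long, .data$freq_hz > 0),
                    ggplot2::aes(x = .data$freq_hz, y = .data$psd,
                                 color = .data$signal)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "frequency (Hz)", y = "grand-average psd")
  }
}
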