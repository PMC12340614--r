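# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an autocorrelation curve
#'
#' @param object A [correlation_curve()].
#' @param log_tau Logarithmic delay axis (default TRUE).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.correlation_curve <- function(object, log_tau = TRUE, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d[d$tau > 0, ],
                       ggplot2::aes(x = .data$tau, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "delay time τ (s)", y = curve_kind(object)) +
    ggplot2::theme_minimal()
  if (log_tau) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a BFi time series
#'
#' @param object A [flow_series()].
#' @param relative Label the y axis as relative BFi.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.flow_series <- function(object, relative = FALSE, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d[d$valid, ],
                  ggplot2::aes(x = .data$time, y = .data$bfi)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "time (s)",
      y = if (relative) "rBFi" else expression(BFi ~ (cm^2 / s)),
      title = attr(object, "modality")) +
    ggplot2::theme_minimal()
}

#' Plot a beat-averaged pulsatile waveform with its interquartile band
#'
#' @param object A `pulsatile_waveform` from [average_waveform()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pulsatile_waveform <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value)) +
    ggplot2::labs(x = "cardiac phase", y = "normalized BFi") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of percent differences against the reference
#'
#' @param object A `bland_altman` from [bland_altman_nonparametric()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  d <- tibble::tibble(index = seq_along(object$differences),
                      diff_pct = object$differences)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$diff_pct)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "black") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "pair", y = "difference (% of reference)") +
    ggplot2::theme_minimal()
}
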