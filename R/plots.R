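#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_pointrange geom_hline
#'   labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a power spectral density
#'
#' @param object A [welch_psd()] result.
#' @param xlim Frequency range shown (Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psd_result <- function(object, xlim = c(0, 100), ...) {
  df <- tibble::tibble(
    freq = rep(object$freqs, each = nrow(object$power)),
    channel = rep(object$channel_labels, length(object$freqs)),
    power = as.vector(object$power)
  )
  df <- df[df$freq >= xlim[1] & df$freq <= xlim[2], ]
  ggplot(df, aes(x = .data$freq, y = .data$power, colour = .data$channel)) +
    geom_line(linewidth = 0.3, show.legend = nrow(object$power) <= 8) +
    labs(x = "frequency (Hz)", y = "PSD (dB, 10log10 µV²/Hz)") +
    theme_minimal()
}

#' Plot posterior coefficient intervals of a fit
#'
#' @param object A `posterior_draws` object.
#' @param pattern Regular expression selecting parameters (default: group
#'   coefficients).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.posterior_draws <- function(object, pattern = "^beta\\[", ...) {
  td <- tidy(object)
  td <- td[grepl(pattern, td$term), ]
  ggplot(td, aes(x = .data$estimate, y = .data$term)) +
    geom_pointrange(aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    geom_hline(yintercept = 0, linetype = 0) +
    labs(x = "posterior median and 95% interval", y = NULL) +
    theme_minimal()
}

#' Plot the per-variant power-difference posteriors of a study
#'
#' Median and 66/95% intervals of the eyes-closed minus eyes-open band power
#' difference for every data variant.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  d <- object$delta_psd
  d$variant <- factor(d$variant, levels = rev(c("REF", "CWL", "AAS", "OBS",
                                                "IAR", "NC")))
  ggplot(d, aes(x = .data$median, y = .data$variant)) +
    geom_pointrange(aes(xmin = .data$l95, xmax = .data$u95), linewidth = 0.4) +
    geom_pointrange(aes(xmin = .data$l66, xmax = .data$u66), linewidth = 1.1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    labs(x = "ΔPSD (dB), EC - EO", y = NULL) +
    theme_minimal()
}
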