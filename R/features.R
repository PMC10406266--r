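#' Frequency bands used in the evaluation
#'
#' Alpha 8-12 Hz, beta 15-25 Hz, gamma 70-80 Hz.
#'
#' @param name `"alpha"`, `"beta"` or `"gamma"`, or `NULL` for the full table.
#' @return Tibble with columns `name`, `lo_hz`, `hi_hz`.
#' @export
band_definition <- function(name = NULL) {
  bands <- tibble::tibble(
    name = c("alpha", "beta", "gamma"),
    lo_hz = c(8, 15, 70),
    hi_hz = c(12, 25, 80)
  )
  if (is.null(name)) return(bands)
  out <- bands[bands$name == name, ]
  if (nrow(out) == 0) abort(sprintf("unknown band '%s'", name))
  out
}

#' Mean band power of a PSD
#'
#' Mean of the dB values over the frequency bins with `lo <= f <= hi`
#' (inclusive at both edges, at grid resolution).
#'
#' @param psd A [welch_psd()] result.
#' @param lo_hz,hi_hz Band edges in Hz, or a one-row [band_definition()]
#'   tibble passed as `lo_hz`.
#' @return Named numeric vector, one dB value per channel.
#' @export
band_mean_power <- function(psd, lo_hz, hi_hz = NULL) {
  if (is.data.frame(lo_hz)) {
    hi_hz <- lo_hz$hi_hz; lo_hz <- lo_hz$lo_hz
  }
  sel <- psd$freqs >= lo_hz & psd$freqs <= hi_hz
  if (!any(sel)) {
    abort(sprintf("band [%g, %g] Hz contains no frequency bins (grid 0-%g Hz).",
                  lo_hz, hi_hz, max(psd$freqs)))
  }
  out <- rowMeans(psd$power[, sel, drop = FALSE])
  names(out) <- psd$channel_labels
  out
}

#' Select summary channels from a topography by z-score
#'
#' Standardizes per-channel values over channels and returns those whose
#' signed z-score exceeds the threshold (1 SD for the resting-state alpha
#' topography, 2 SD for the tapping and VEP topographies). Channels are
#' ordered by |z| descending, ties broken by label order, so the selection is
#' deterministic and permutation-invariant.
#'
#' @param values Named numeric vector of per-channel topography values.
#' @param z_threshold Selection threshold in SD units (typically 1 or 2).
#' @param sign `+1` to select strongly positive channels, `-1` strongly
#'   negative ones.
#' @return Character vector of selected channel labels (possibly empty, with
#'   a warning when the topography is flat).
#' @export
select_summary_channels <- function(values, z_threshold = 1, sign = 1) {
  if (length(values) < 3) abort("channel selection needs >= 3 channels.")
  if (is.null(names(values))) names(values) <- paste0("ch", seq_along(values))
  s <- sd(values)
  if (s < 1e-12) {
    warn("zero variance across channels; empty selection.")
    return(character())
  }
  z <- (values - mean(values)) / s
  keep <- sign * z > z_threshold
  sel <- names(values)[keep]
  o <- order(-abs(z[keep]), sel)
  sel[o]
}

#' Average PSDs over a set of summary channels
#'
#' Bin-wise mean of the per-channel spectra, in the dB domain. Averaging
#' spectra (not time-domain signals) preserves non-phase-locked power.
#'
#' @param psd A multi-channel [welch_psd()] result.
#' @param channels Character vector of selected channel labels.
#' @return A single-channel `psd_result`.
#' @export
summary_channel_psd <- function(psd, channels) {
  if (length(channels) == 0) abort("summary channel set is empty.")
  idx <- match(channels, psd$channel_labels)
  if (anyNA(idx)) {
    abort(sprintf("unknown channel label(s): %s",
                  paste(channels[is.na(idx)], collapse = ", ")))
  }
  structure(list(
    freqs = psd$freqs,
    power = matrix(colMeans(psd$power[idx, , drop = FALSE]), nrow = 1),
    channel_labels = "summary",
    params = psd$params
  ), class = "psd_result")
}

#' Contralateral / ipsilateral VEP waves and their difference
#'
#' For quadrant checkerboard stimulation, the contralateral wave is the mean
#' over left-hemisphere channels during right-field trials and right-
#' hemisphere channels during left-field trials; the ipsilateral wave is the
#' converse; the difference wave is contra minus ipsi.
#'
#' @param epochs An [epoch_data()] result whose events carry quadrant
#'   conditions `LU`, `LL`, `RU`, `RL`.
#' @param hemisphere_map Named list with `left` and `right` character vectors
#'   of channel labels.
#' @return Tibble with columns `time_s`, `contra`, `ipsi`, `difference` (uV).
#' @export
contra_ipsi_waves <- function(epochs, hemisphere_map) {
  conds <- unique(epochs$events$condition)
  need <- c("LU", "LL", "RU", "RL")
  if (!all(need %in% conds)) {
    abort(sprintf("all four quadrant conditions required; missing: %s",
                  paste(setdiff(need, conds), collapse = ", ")))
  }
  if (!all(c("left", "right") %in% names(hemisphere_map))) {
    abort("hemisphere_map must contain `left` and `right` label sets.")
  }
  li <- match(hemisphere_map$left, epochs$channel_labels)
  ri <- match(hemisphere_map$right, epochs$channel_labels)
  if (anyNA(li) || anyNA(ri)) abort("hemisphere_map contains unknown labels.")
  lf <- epochs$events$condition %in% c("LU", "LL")   # left-field trials
  rf <- epochs$events$condition %in% c("RU", "RL")
  avg <- function(trials, chans) {
    apply(epochs$data[trials, chans, , drop = FALSE], 3, mean)
  }
  # stimulus side weighted equally regardless of trial counts
  contra <- (avg(rf, li) + avg(lf, ri)) / 2
  ipsi <- (avg(lf, li) + avg(rf, ri)) / 2
  nt <- dim(epochs$data)[3]
  tibble::tibble(
    time_s = epochs$tmin_s + (seq_len(nt) - 1) / epochs$fs,
    contra = contra, ipsi = ipsi, difference = contra - ipsi
  )
}

#' Mean amplitude in a time window
#'
#' Arithmetic mean of the samples whose latencies fall inside the window,
#' closed at both ends at millisecond resolution.
#'
#' @param x Numeric series (one epoch or an ERP).
#' @param window_ms Length-2 window in ms.
#' @param fs Sampling rate (Hz).
#' @param t0_s Latency of the first sample of `x` in seconds (e.g. -0.2 for
#'   an epoch starting 200 ms before the stimulus).
#' @return Mean amplitude (uV).
#' @export
window_mean_amplitude <- function(x, window_ms, fs, t0_s = 0) {
  t_ms <- (t0_s + (seq_along(x) - 1) / fs) * 1000
  sel <- t_ms >= window_ms[1] - 1e-9 & t_ms <= window_ms[2] + 1e-9
  if (!any(sel) || window_ms[1] < min(t_ms) - 1e-9 || window_ms[2] > max(t_ms) + 1e-9) {
    abort(sprintf("window [%g, %g] ms lies outside the epoch [%g, %g] ms.",
                  window_ms[1], window_ms[2], min(t_ms), max(t_ms)))
  }
  mean(x[sel])
}

#' RMS-ratio signal-to-noise of an evoked response
#'
#' SNR is the maximum of a sliding RMS (sub-window `rms_span_ms`) over the
#' peak window, divided by the mean sliding RMS over the baseline window.
#' Scale-invariant; errors on a degenerate (zero) baseline.
#'
#' @param x Numeric series (trial or ERP).
#' @param peak_window_ms,baseline_window_ms Length-2 windows in ms.
#' @param fs Sampling rate (Hz).
#' @param t0_s Latency of the first sample (s).
#' @param rms_span_ms Sliding RMS support (default 20 ms).
#' @return SNR ratio (dimensionless, > 0).
#' @export
snr_rms <- function(x, peak_window_ms, baseline_window_ms = c(-200, 0),
                    fs, t0_s = -0.2, rms_span_ms = 20) {
  span <- max(1L, round(rms_span_ms / 1000 * fs))
  run_rms <- sqrt(as.numeric(stats::filter(x^2, rep(1 / span, span), sides = 2)))
  t_ms <- (t0_s + (seq_along(x) - 1) / fs) * 1000
  pk <- t_ms >= peak_window_ms[1] - 1e-9 & t_ms <= peak_window_ms[2] + 1e-9
  bl <- t_ms >= baseline_window_ms[1] - 1e-9 & t_ms <= baseline_window_ms[2] + 1e-9
  if (!any(pk) || !any(bl)) abort("peak/baseline windows lie outside the epoch.")
  pk_vals <- run_rms[pk]; bl_vals <- run_rms[bl]
  pk_vals <- pk_vals[!is.na(pk_vals)]; bl_vals <- bl_vals[!is.na(bl_vals)]
  denom <- mean(bl_vals)
  if (!is.finite(denom) || denom < 1e-12) {
    abort("baseline RMS is zero; SNR undefined for degenerate input.")
  }
  max(pk_vals) / denom
}

#' Root-mean-square deviation between two series
#'
#' @param a,b Equal-length numeric series (uV).
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmsd <- function(a, b) {
  if (length(a) != length(b)) abort("series lengths differ.")
  sqrt(mean((a - b)^2))
}
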