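#' Design a Hamming-windowed-sinc low-pass FIR filter
#'
#' Filter length follows Fred Harris' rule-of-thumb
#' `N = atten_db / (22 * transition_hz / fs)`, rounded up to the next odd
#' integer so the filter is linear-phase with an integer group delay.
#' Coefficients are normalized to unit DC gain. At 30 dB attenuation,
#' a 1 Hz transition band and fs = 500 Hz the rule yields 683 taps.
#'
#' @param cutoff_hz Cutoff (-6 dB) frequency, 0 < cutoff < fs/2.
#' @param fs Sampling rate (Hz).
#' @param stopband_atten_db Desired stopband attenuation (dB), default 30.
#' @param transition_hz Transition bandwidth (Hz), default 1.
#' @return Numeric coefficient vector of odd length, summing to 1.
#' @export
design_lowpass_fir <- function(cutoff_hz, fs, stopband_atten_db = 30,
                               transition_hz = 1) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort("cutoff_hz must lie strictly between 0 and fs/2.")
  }
  if (transition_hz <= 0) abort("transition_hz must be positive.")
  n <- ceiling(stopband_atten_db / (22 * transition_hz / fs))
  if (n %% 2 == 0) n <- n + 1
  m <- (n - 1) / 2
  k <- -m:m
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc(2 * fc * k)
  w <- 0.54 - 0.46 * cos(2 * pi * (k + m) / (n - 1))  # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase FIR filtering
#'
#' Applies an odd-length linear-phase FIR filter by centered convolution, so
#' the output has no group delay. Edges are handled by reflecting the signal.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param h Odd-length FIR coefficients.
#' @return Filtered object of the same shape.
#' @export
filter_zero_phase <- function(x, h) {
  if (length(h) %% 2 == 0) abort("filter length must be odd for zero-phase use.")
  if (is.matrix(x)) {
    return(t(apply(x, 1, filter_zero_phase, h = h)))
  }
  n <- length(x)
  m <- (length(h) - 1) / 2
  if (length(h) > n) abort("filter is longer than the signal.")
  pad <- c(rev(x[2:(m + 1)]), x, rev(x[(n - m):(n - 1)]))
  out <- stats::filter(pad, h, method = "convolution", sides = 2)
  as.numeric(out[(m + 1):(m + n)])
}

#' Frequency response magnitude of an FIR filter
#'
#' @param h Coefficients.
#' @param fs Sampling rate (Hz).
#' @param n_points Frequency grid size.
#' @return Tibble with `freq` (Hz) and `gain_db`.
#' @export
fir_response <- function(h, fs, n_points = 4096) {
  hpad <- c(h, numeric(2 * n_points - length(h)))
  H <- fft(hpad)[seq_len(n_points)]
  tibble::tibble(
    freq = seq(0, fs / 2, length.out = n_points),
    gain_db = 20 * log10(pmax(Mod(H), 1e-12))
  )
}

#' Downsample a recording
#'
#' Anti-aliased resampling: a zero-phase low-pass at 0.9 x the new Nyquist
#' frequency followed by decimation for integer rate ratios; non-integer
#' rational ratios use polyphase resampling from the signal package. Marker
#' samples are rescaled by the rate ratio and rounded to the nearest sample.
#'
#' @param rec An [new_recording()] object.
#' @param new_fs Target rate (Hz), `new_fs <= fs`.
#' @param markers Optional [new_markers()] to rescale alongside.
#' @return The resampled recording, or a list `(recording, markers)` when
#'   markers are supplied.
#' @export
resample_recording <- function(rec, new_fs, markers = NULL) {
  if (new_fs > rec$fs) abort("upsampling is not supported (new_fs > fs).")
  if (new_fs == rec$fs) {
    return(if (is.null(markers)) rec else list(recording = rec, markers = markers))
  }
  ratio <- rec$fs / new_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    k <- as.integer(round(ratio))
    h <- design_lowpass_fir(0.9 * new_fs / 2, rec$fs,
                            stopband_atten_db = 60,
                            transition_hz = 0.1 * new_fs / 2)
    filt <- filter_zero_phase(rec$data, h)
    newdata <- filt[, seq(1, ncol(rec$data), by = k), drop = FALSE]
  } else {
    p <- round(new_fs); q <- round(rec$fs)
    g <- gcd(p, q)
    newdata <- t(apply(rec$data, 1, function(x) {
      as.numeric(signal::resample(x, p / g, q / g))
    }))
  }
  out <- new_recording(newdata, new_fs, rec$channel_labels, rec$channel_roles,
                       rec$reference)
  if (is.null(markers)) return(out)
  mk <- markers
  mk$sample <- as.integer(round(mk$sample * new_fs / rec$fs))
  list(recording = out, markers = mk)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Re-reference scalp channels to the common average
#'
#' Subtracts the instantaneous mean of the scalp channels from every scalp
#' channel; CWL and ECG channels are untouched. Idempotent; after the
#' operation the scalp channels sum to zero at every sample.
#'
#' @param rec An [new_recording()] object with at least two scalp channels.
#' @return Recording with `reference = "average"`.
#' @export
rereference_average <- function(rec) {
  i_scalp <- channels_with_role(rec, "scalp")
  if (length(i_scalp) < 2) abort("average reference needs at least 2 scalp channels.")
  data <- rec$data
  avg <- colMeans(data[i_scalp, , drop = FALSE])
  data[i_scalp, ] <- sweep(data[i_scalp, , drop = FALSE], 2, avg)
  new_recording(data, rec$fs, rec$channel_labels, rec$channel_roles, "average")
}

#' Cut a recording into event-locked epochs
#'
#' Windows are half-open in samples: `[event + round(tmin*fs),
#' event + round(tmax*fs))`. Events whose window does not fit inside the
#' recording are dropped (logged), never padded.
#'
#' @param rec An [new_recording()] object.
#' @param events Integer vector of 0-based event samples, or an
#'   [new_markers()]-style tibble with `sample` (and optionally `condition`
#'   or `label`) columns.
#' @param tmin_s,tmax_s Window edges in seconds relative to the event.
#' @return List of class `epoch_set`: `data` (epochs x channels x samples
#'   array), `tmin_s`, `tmax_s`, `fs`, `events` (tibble of surviving events).
#' @export
epoch_data <- function(rec, events, tmin_s, tmax_s) {
  if (is.numeric(events)) {
    events <- tibble::tibble(sample = as.integer(events),
                             condition = NA_character_)
  }
  if ("label" %in% names(events) && !"condition" %in% names(events)) {
    events$condition <- events$label
  }
  fs <- rec$fs
  start <- events$sample + round(tmin_s * fs)
  stop <- events$sample + round(tmax_s * fs)  # exclusive
  len <- unique(stop - start)[1]
  ok <- start >= 0 & stop <= n_samples(rec)
  if (any(!ok)) {
    log_msg("info", sprintf("dropping %d boundary epoch(s)", sum(!ok)))
  }
  if (!any(ok)) abort("no epochs survive the recording boundaries.")
  events <- events[ok, , drop = FALSE]
  start <- start[ok]
  arr <- array(NA_real_, dim = c(length(start), nrow(rec$data), len))
  for (i in seq_along(start)) {
    arr[i, , ] <- rec$data[, (start[i] + 1):(start[i] + len), drop = FALSE]
  }
  structure(list(data = arr, tmin_s = tmin_s, tmax_s = tmax_s, fs = fs,
                 events = tibble::as_tibble(events),
                 channel_labels = rec$channel_labels),
            class = "epoch_set")
}

#' Welch power spectral density estimate
#'
#' Mean of Hamming-tapered periodogram segments with 50% overlap, density
#' scaling (power per Hz), converted to decibels (`10*log10`). Inputs shorter
#' than one segment are zero-padded to the segment length and estimated from
#' that single padded segment; the applied padding is recorded in the result.
#' Zero-power bins are floored at -300 dB to keep downstream models finite.
#'
#' Multi-channel summaries must average per-channel PSDs (see
#' [summary_channel_psd()]), never the time-domain signals.
#'
#' @param x Numeric vector, or channels x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param nperseg Segment length (samples), default `2^12`.
#' @param overlap Fractional segment overlap, default 0.5.
#' @param channel_labels Optional channel names for matrix input.
#' @return A list of class `psd_result`: `freqs` (Hz), `power`
#'   (channels x freqs matrix, dB of uV^2/Hz), `params` (list with `nperseg`,
#'   `overlap`, `taper`, `pad`, `n_segments`).
#' @export
welch_psd <- function(x, fs, nperseg = 4096, overlap = 0.5,
                      channel_labels = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < 1) abort("input must contain at least one sample.")
  pad <- 0L
  if (n < nperseg) {
    pad <- as.integer(nperseg - n)
    x <- cbind(x, matrix(0, nrow(x), pad))
    n <- nperseg
  }
  hop <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))  # Hamming
  u <- sum(w^2)                       # density normalization
  nfreq <- nperseg %/% 2 + 1L
  acc <- matrix(0, nrow(x), nfreq)
  for (s in starts) {
    seg <- x[, s:(s + nperseg - 1L), drop = FALSE]
    seg <- sweep(seg, 1, rowMeans(seg))          # per-segment detrend (mean)
    seg <- sweep(seg, 2, w, `*`)
    ft <- t(stats::mvfft(t(seg)))[, seq_len(nfreq), drop = FALSE]
    p <- (Mod(ft)^2) / (fs * u)
    p[, 2:(nfreq - 1L)] <- 2 * p[, 2:(nfreq - 1L), drop = FALSE]  # one-sided
    acc <- acc + p
  }
  psd <- acc / length(starts)
  power_db <- 10 * log10(pmax(psd, 1e-30))
  power_db[power_db < -300] <- -300
  structure(list(
    freqs = seq(0, fs / 2, length.out = nfreq),
    power = power_db,
    channel_labels = channel_labels %||% rownames(x) %||%
      paste0("ch", seq_len(nrow(x))),
    params = list(nperseg = nperseg, overlap = overlap, taper = "hamming",
                  pad = pad, n_segments = length(starts), fs = fs)
  ), class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result> %d channel(s), %d bins 0-%.4g Hz (df = %.4g Hz), %d segment(s), pad %d\n",
    nrow(x$power), length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1],
    x$params$n_segments, x$params$pad
  ))
  invisible(x)
}
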