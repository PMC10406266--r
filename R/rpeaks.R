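#' Detect R peaks in an ECG trace
#'
#' A derivative-energy detector: the ECG is band-passed to 5-15 Hz
#' (zero-phase FIR), differentiated, squared and integrated over a 150-ms
#' moving window; peaks of the energy envelope are picked with an adaptive
#' signal/noise threshold and a 300-ms refractory period, then each detection
#' is refined to the largest absolute band-passed deflection nearby. The
#' detector is invariant to ECG polarity.
#'
#' @param ecg Single-channel numeric vector (uV).
#' @param fs Sampling rate (Hz), >= 100.
#' @return Sorted integer vector of 0-based R-peak samples (empty, with a
#'   warning, for flat input).
#' @export
detect_rpeaks <- function(ecg, fs) {
  if (fs < 100) abort("detect_rpeaks needs fs >= 100 Hz.")
  if (!all(is.finite(ecg))) abort("ECG contains non-finite values.")
  if (sd(ecg) < 1e-12) {
    warn("flat ECG signal; no R peaks detected.")
    return(integer())
  }
  h_hi <- design_lowpass_fir(15, fs, stopband_atten_db = 40, transition_hz = 5)
  h_lo <- design_lowpass_fir(5, fs, stopband_atten_db = 40, transition_hz = 5)
  bp <- filter_zero_phase(ecg, h_hi) - filter_zero_phase(ecg, h_lo)
  d <- c(0, diff(bp)) * fs
  env <- stats::filter(d^2, rep(1 / round(0.15 * fs), round(0.15 * fs)), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)

  refract <- round(0.3 * fs)
  # local maxima of the envelope
  is_peak <- c(FALSE, diff(sign(diff(env))) < 0, FALSE) & env > 0
  cand <- which(is_peak)
  if (length(cand) == 0) {
    warn("no envelope peaks found; no R peaks detected.")
    return(integer())
  }
  spki <- max(env[seq_len(min(length(env), 2 * fs))]) * 0.8
  npki <- spki / 8
  thr <- npki + 0.25 * (spki - npki)
  accepted <- integer()
  last <- -Inf
  for (p in cand) {
    if (env[p] >= thr) {
      if (p - last > refract) {
        accepted <- c(accepted, p)
        last <- p
        spki <- 0.125 * env[p] + 0.875 * spki
      } else if (env[p] > env[last]) {   # same beat, keep the stronger peak
        accepted[length(accepted)] <- p
        last <- p
        spki <- 0.125 * env[p] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * env[p] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(accepted) == 0) {
    warn("no peaks exceeded the adaptive threshold.")
    return(integer())
  }
  # refine to the strongest absolute band-passed deflection within +/-80 ms
  half <- round(0.08 * fs)
  peaks <- vapply(accepted, function(p) {
    a <- max(1L, p - half); b <- min(length(bp), p + half)
    as.integer(a + which.max(abs(bp[a:b])) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory period after refinement, keeping stronger peaks
  if (length(peaks) > 1) {
    keep <- rep(TRUE, length(peaks))
    i <- 1L
    for (j in 2:length(peaks)) {
      if (peaks[j] - peaks[i] < refract) {
        if (abs(bp[peaks[j]]) > abs(bp[peaks[i]])) { keep[i] <- FALSE; i <- j }
        else keep[j] <- FALSE
      } else i <- j
    }
    peaks <- peaks[keep]
  }
  as.integer(peaks - 1L)
}
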