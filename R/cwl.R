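#' Carbon-wire loop regression design
#'
#' Parameters of the windowed reference regression: Hann-tapered windows of
#' `window_s` seconds at 50% hop, loop regressors shifted over a symmetric
#' lag grid of `max_lag_s` at `lag_step`-sample resolution, plus a per-window
#' intercept.
#'
#' @param window_s Window duration in seconds (default 4).
#' @param max_lag_s Maximum regressor delay in seconds (default 0.021).
#' @param lag_step Lag grid step in samples (default 1).
#' @return A list of class `cwl_design`.
#' @export
cwl_design <- function(window_s = 4, max_lag_s = 0.021, lag_step = 1L) {
  if (window_s <= 2 * max_lag_s) abort("window_s must exceed 2 * max_lag_s.")
  if (lag_step < 1) abort("lag_step must be >= 1 sample.")
  structure(list(window_s = window_s, max_lag_s = max_lag_s,
                 lag_step = as.integer(lag_step), taper = "hann"),
            class = "cwl_design")
}

#' Carbon-wire loop (CWL) reference regression
#'
#' Removes MR-induced artifacts by regressing the six artifact-only loop
#' signals and their time-shifted copies out of each EEG channel,
#' independently, across overlapping Hann-tapered windows. Per window the
#' tapered EEG segment is least-squares fitted on the tapered lagged loop
#' regressors plus an intercept; the loop contribution of the fit (the
#' intercept is excluded, so a zero-regressor run is an exact identity) is
#' subtracted and windows are recombined by weighted overlap-add, normalized
#' by the accumulated taper so edge half-windows are handled exactly.
#'
#' @param rec An [new_recording()] object.
#' @param cwl 6 x samples loop matrix, sample-aligned with `rec`. Defaults to
#'   the recording's own `cwl`-role channels.
#' @param design A [cwl_design()] object.
#' @param channels Channels to correct; defaults to scalp and ECG channels.
#' @return The corrected recording.
#' @export
cwl_regress <- function(rec, cwl = NULL, design = cwl_design(),
                        channels = NULL) {
  if (is.null(cwl)) {
    i_cwl <- channels_with_role(rec, "cwl")
    if (length(i_cwl) != 6) {
      abort("Recording has no 6-loop cwl channel set; supply `cwl` explicitly.")
    }
    cwl <- rec$data[i_cwl, , drop = FALSE]
  }
  cwl <- as.matrix(cwl)
  n <- n_samples(rec)
  if (ncol(cwl) != n) abort("cwl matrix must be sample-aligned with the recording.")
  if (is.null(channels)) {
    channels <- which(rec$channel_roles %in% c("scalp", "ecg"))
  }
  fs <- rec$fs
  W <- min(round(design$window_s * fs), n)
  if (W %% 2 == 1) W <- W - 1L
  hop <- W %/% 2L
  L <- round(design$max_lag_s * fs)
  lags <- seq(-L, L, by = design$lag_step)
  nl <- length(lags)
  # strictly positive Hann taper: every sample of every window carries weight,
  # so the weight-normalized overlap-add covers the recording edges exactly
  taper <- 0.5 * (1 - cos(2 * pi * (1:W) / (W + 1)))

  # all windows lie fully inside the recording; an extra final window pinned
  # at the end covers the tail (half-window overlap there)
  starts <- unique(c(seq(1L, n - W + 1L, by = hop), n - W + 1L))
  Xfull <- cbind(matrix(0, 6, L), cwl, matrix(0, 6, L))
  Y <- rec$data[channels, , drop = FALSE]
  acc <- matrix(0, length(channels), n)
  wsum <- numeric(n)

  X <- matrix(0, W, 6 * nl)
  for (s in starts) {
    for (j in 1:6) {
      for (li in seq_len(nl)) {
        # column holds loop j delayed by lags[li] samples
        X[, (j - 1) * nl + li] <- Xfull[j, (s + L - lags[li]):(s + L - lags[li] + W - 1L)]
      }
    }
    Xw <- X * taper
    Yw <- t(Y[, s:(s + W - 1L), drop = FALSE]) * taper
    D <- cbind(taper, Xw)                 # intercept column = taper
    G <- crossprod(D)
    rhs <- crossprod(D, Yw)
    B <- tryCatch(solve(G, rhs), error = function(e) {
      log_msg("info", "rank-deficient CWL design; ridge fallback")
      solve(G + diag(1e-8 * mean(diag(G)) + 1e-12, ncol(G)), rhs)
    })
    art <- X %*% B[-1, , drop = FALSE]    # loop contribution, untapered
    idx <- s:(s + W - 1L)
    acc[, idx] <- acc[, idx] + t(art * taper)
    wsum[idx] <- wsum[idx] + taper
  }
  artifact <- sweep(acc, 2, 1 / wsum, `*`)
  data <- rec$data
  data[channels, ] <- data[channels, , drop = FALSE] - artifact
  new_recording(data, fs, rec$channel_labels, rec$channel_roles, rec$reference)
}
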