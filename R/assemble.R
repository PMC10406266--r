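#' Synthetic ECG trace
#'
#' A stereotyped QRS complex (sharp R wave flanked by Q and S lobes) plus a
#' low broad T wave at every R-peak sample. Used as the ECG channel of
#' assembled sessions; R-peak detection operates on this trace.
#'
#' @param rpeaks Sorted 0-based R-peak samples.
#' @param fs Sampling rate (Hz).
#' @param n_samples Output length.
#' @param amp R-wave amplitude (uV).
#' @return Numeric vector.
#' @export
simulate_ecg_trace <- function(rpeaks, fs, n_samples, amp = 600) {
  t <- seq(-0.3, 0.5, by = 1 / fs)
  qrs <- amp * (exp(-(t)^2 / (2 * 0.008^2)) -
                  0.25 * exp(-(t + 0.028)^2 / (2 * 0.010^2)) -
                  0.30 * exp(-(t - 0.030)^2 / (2 * 0.010^2)) +
                  0.18 * exp(-(t - 0.28)^2 / (2 * 0.045^2)))
  pre <- sum(t < 0)
  out <- numeric(n_samples)
  for (r in rpeaks) {
    a <- r - pre + 1L
    idx <- a:(a + length(qrs) - 1L)
    keep <- idx >= 1L & idx <= n_samples
    out[idx[keep]] <- out[idx[keep]] + qrs[keep]
  }
  out
}

#' Assemble a complete synthetic EEG-fMRI session
#'
#' Builds a full recording with known ground truth: task-locked neural
#' activity plus imaging, BCG, helium-pump and (for the tapping task) motion
#' artifacts on the scalp channels; six carbon-wire loop channels carrying
#' lag-shifted mixtures of the same artifact sources but no neural signal; an
#' ECG channel; white sensor noise everywhere; and volume/task markers. The
#' decomposition is exact: `data == neural + imaging + bcg + pump + motion +
#' noise`, per sample.
#'
#' @param config A [session_config()] object. `config$seed` fixes all
#'   randomness.
#' @return A list of class `eeg_session` with elements `recording`
#'   ([new_recording()]), `markers` ([new_markers()]) and `ground_truth`
#'   (class `ground_truth`: `neural`, `artifacts` (named list of full-channel
#'   matrices), `noise`, `rpeak_samples`, `events`, `sources`, `config`).
#' @export
assemble_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  seed <- config$seed
  fs <- config$fs_hz
  layout <- scalp_layout(config$n_channels)
  nc <- nrow(layout)

  neur <- simulate_neural(config$task, config$neural, fs, config, layout,
                          seed = child_seed(seed, 1))
  # round the session up to a whole number of volumes
  tr_samp <- round(fs * config$tr_s)
  n <- ceiling(ncol(neur$signal) / tr_samp) * tr_samp
  pad <- n - ncol(neur$signal)
  if (pad > 0) neur$signal <- cbind(neur$signal, matrix(0, nc, pad))
  duration_s <- n / fs

  n_all <- nc + 6L + 1L
  i_scalp <- seq_len(nc); i_cwl <- nc + 1:6; i_ecg <- nc + 7L
  labels <- c(layout$label, paste0("CWL", 1:6), "ECG")
  roles <- c(rep("scalp", nc), rep("cwl", 6), "ecg")

  rpeaks <- simulate_rpeaks(duration_s, config$hr_mean_bpm, config$hr_sd_bpm,
                            seed = child_seed(seed, 2), fs = fs)

  with_local_seed(child_seed(seed, 3), {
    g_img <- runif(nc, 0.7, 1.0)
    g_img_ecg <- runif(1, 0.8, 1.2)
    g_bcg <- 0.55 + 0.45 * gaussian_topography(layout, c(0, -0.5), sigma = 0.8)
    g_bcg <- g_bcg / max(g_bcg) * runif(nc, 0.92, 1.0)
    g_pump <- runif(nc, 0.6, 1.0)
    g_pump_ecg <- runif(1, 0.3, 0.6)
    g_motion <- runif(nc, 0.5, 1.0)
    cwl_weights <- matrix(runif(24, 0.5, 1.5), 6, 4)
    cwl_lags <- matrix(runif(24, -10, 10), 6, 4)
  })

  imaging <- simulate_imaging_artifact(config$artifact, fs, duration_s, g_img)
  src_img <- attr(imaging, "source")

  bcg_scalp <- simulate_bcg(rpeaks, config$artifact, fs, n,
                            topography = g_bcg,
                            seed = child_seed(seed, 4))
  src_bcg <- attr(bcg_scalp, "source")

  pump <- simulate_pump(config$artifact, fs, duration_s,
                        gains = g_pump, seed = child_seed(seed, 5))
  src_pump <- attr(pump, "source")

  src_motion <- motion_source(config, neur$events, fs, n, child_seed(seed, 6))

  cwl <- simulate_cwl_reference(
    sources = list(imaging = src_img, bcg = src_bcg, pump = src_pump,
                   motion = src_motion),
    lags_ms = cwl_lags, weights = cwl_weights,
    noise_sd = config$cwl_noise_sd, fs = fs, seed = child_seed(seed, 7)
  )

  # full-channel component matrices (scalp rows, loop rows, ECG row); the ECG
  # channel's cardiac trace is heartbeat-locked and lives in the bcg component
  full <- function(scalp, cwl_part, ecg_row) {
    rbind(scalp, cwl_part, matrix(ecg_row, 1))
  }
  imaging_f <- full(imaging, cwl$per_source$imaging, src_img * g_img_ecg)
  bcg_f <- full(bcg_scalp, cwl$per_source$bcg,
                simulate_ecg_trace(rpeaks, fs, n))
  pump_f <- full(matrix(pump, nrow = nc), cwl$per_source$pump,
                 src_pump * g_pump_ecg)
  motion_f <- full(outer(g_motion, src_motion), cwl$per_source$motion,
                   numeric(n))

  neural_f <- rbind(neur$signal, matrix(0, 7, n))

  noise <- with_local_seed(child_seed(seed, 8), {
    m <- matrix(rnorm(n_all * n, 0, config$sensor_noise_sd), n_all, n)
    m[i_cwl, ] <- cwl$noise
    m[i_ecg, ] <- m[i_ecg, ] * 5  # ECG electrode noise floor is higher
    m
  })

  artifacts <- list(imaging = imaging_f, bcg = bcg_f, pump = pump_f,
                    motion = motion_f)
  # same left-fold as the conservation check so the decomposition is bit-exact
  data <- Reduce(`+`, c(list(neural_f), artifacts, list(noise)))
  rec <- new_recording(data, fs, labels, roles, reference = "FCz")

  vol_samples <- seq(0L, n - 1L, by = tr_samp)
  markers <- new_markers(
    kind = c(rep("volume", length(vol_samples)), neur$events$kind),
    label = c(rep(config$volume_marker, length(vol_samples)), neur$events$condition),
    sample = c(vol_samples, neur$events$sample)
  )

  gt <- structure(list(
    neural = neural_f,
    artifacts = artifacts,
    noise = noise,
    rpeak_samples = rpeaks,
    events = neur$events,
    sources = list(imaging = src_img, bcg = src_bcg, pump = src_pump,
                   motion = src_motion),
    layout = layout,
    config = config
  ), class = "ground_truth")

  structure(list(recording = rec, markers = markers, ground_truth = gt),
            class = "eeg_session")
}

# band-limited (1-25 Hz) random bursts during tapping blocks; zero elsewhere
# and zero for the other tasks
motion_source <- function(config, events, fs, n, seed) {
  if (config$task != "tapping" || config$artifact$motion_amp == 0) {
    return(numeric(n))
  }
  env <- condition_envelope(n, fs, events, on_len_s = 3,
                            level = function(cond) 1, base_level = 0)
  carrier <- band_noise(n, fs, 1, 25, seed)
  src <- carrier * env
  if (all(src == 0)) return(src)
  src / max(abs(src)) * config$artifact$motion_amp
}

#' Reference (artifact-free) variant of a session
#'
#' The clean benchmark signal: neural activity plus sensor noise on the scalp
#' channels, mirroring a recording taken outside the scanner.
#'
#' @param session An [assemble_session()] result.
#' @return An [new_recording()] with the session's scalp channels only.
#' @export
reference_recording <- function(session) {
  gt <- session$ground_truth
  i_scalp <- which(session$recording$channel_roles == "scalp")
  new_recording(
    gt$neural[i_scalp, , drop = FALSE] + gt$noise[i_scalp, , drop = FALSE],
    session$recording$fs,
    session$recording$channel_labels[i_scalp],
    rep("scalp", length(i_scalp)),
    reference = session$recording$reference
  )
}
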