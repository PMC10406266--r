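#' Simulate heartbeat (R-peak) times
#'
#' Inter-beat intervals are drawn i.i.d. from a normal distribution truncated
#' below at 300 ms; the first peak falls within the first two seconds.
#'
#' @param duration_s Session duration (s); must accommodate at least one beat.
#' @param hr_mean_bpm Mean heart rate (beats per minute), > 0.
#' @param hr_sd_bpm Between-beat heart-rate SD (bpm), >= 0. Zero gives exactly
#'   periodic beats.
#' @param seed Integer seed.
#' @param fs Sampling rate used to express peaks as sample indices.
#' @return Sorted integer vector of 0-based R-peak samples.
#' @export
simulate_rpeaks <- function(duration_s, hr_mean_bpm = 65, hr_sd_bpm = 3,
                            seed = 1L, fs = 5000) {
  if (hr_mean_bpm <= 0) abort("hr_mean_bpm must be positive.")
  if (hr_sd_bpm < 0) abort("hr_sd_bpm must be non-negative.")
  ibi_mean <- 60 / hr_mean_bpm
  if (duration_s < 0.3 || duration_s <= ibi_mean / 2) {
    abort(sprintf("duration %.3g s is too short for a single beat.", duration_s))
  }
  ibi_sd <- 60 * hr_sd_bpm / hr_mean_bpm^2
  with_local_seed(seed, {
    first <- if (hr_sd_bpm == 0) min(ibi_mean, 1) else runif(1, 0.2, min(2, duration_s))
    times <- first
    repeat {
      ibi <- rnorm(1, ibi_mean, ibi_sd)
      while (ibi < 0.3) ibi <- rnorm(1, ibi_mean, ibi_sd)  # truncation floor
      nxt <- times[length(times)] + ibi
      if (nxt >= duration_s) break
      times <- c(times, nxt)
    }
    as.integer(round(times * fs))
  })
}

#' Simulate the MR imaging (gradient) artifact
#'
#' A deterministic, TR-periodic sum of cosines at the slice-frequency
#' harmonics convolved with volume-frequency harmonics, i.e. components at
#' `k * f_slice +/- m * f_volume`. Phases are TR-locked, so the waveform is
#' exactly periodic in the volume repetition time; the peak amplitude on a
#' gain-1 channel equals `params$imaging_amp`.
#'
#' @param params An [artifact_params()] object.
#' @param fs Sampling rate (Hz); must exceed twice the highest harmonic.
#' @param duration_s Duration (s).
#' @param gains Per-channel coupling gains (numeric vector).
#' @return channels x samples matrix with attribute `"source"` (the gain-1
#'   source waveform).
#' @export
simulate_imaging_artifact <- function(params, fs, duration_s, gains) {
  ks <- seq_len(params$n_harmonics_slice)
  ms <- 0:params$n_harmonics_volume
  grid <- expand.grid(k = ks, m = ms)
  freqs <- c(grid$k * params$slice_freq_hz + grid$m * params$volume_freq_hz,
             with(grid[grid$m > 0, , drop = FALSE],
                  k * params$slice_freq_hz - m * params$volume_freq_hz))
  amps <- c(1 / (grid$k * (1 + grid$m)),
            with(grid[grid$m > 0, , drop = FALSE], 1 / (k * (1 + m))))
  phases <- 0.7 * c(grid$k, grid$k[grid$m > 0]) + 1.3 * c(grid$m, grid$m[grid$m > 0])
  if (max(freqs) >= fs / 2) {
    abort(sprintf("Highest imaging harmonic (%.1f Hz) violates the Nyquist limit at fs = %g Hz.",
                  max(freqs), fs))
  }
  period <- round(fs / params$volume_freq_hz)
  t <- (0:(period - 1)) / fs
  base <- numeric(period)
  for (i in seq_along(freqs)) {
    base <- base + amps[i] * cos(2 * pi * freqs[i] * t + phases[i])
  }
  base <- base / max(abs(base)) * params$imaging_amp
  n <- round(duration_s * fs)
  source <- rep_len(base, n)
  out <- outer(as.numeric(gains), source)
  attr(out, "source") <- source
  out
}

#' Beat template of the simulated BCG artifact
#'
#' Sum of Gaussian-windowed oscillations on a [-0.2, 0.5] s support around the
#' (delayed) beat anchor, tapered at the edges, scaled to `params$bcg_amp`
#' peak amplitude.
#'
#' @param params An [artifact_params()] object.
#' @param fs Sampling rate (Hz).
#' @return List with `waveform` (numeric), `pre` and `post` (sample counts
#'   before/after the anchor).
#' @export
bcg_template <- function(params, fs) {
  pre_s <- 0.2; post_s <- 0.5
  pre <- round(pre_s * fs); post <- round(post_s * fs)
  t <- seq(-pre, post - 1) / fs
  h <- numeric(length(t))
  for (i in seq_len(nrow(params$bcg_components))) {
    cc <- params$bcg_components[i, ]
    h <- h + cc$amp * exp(-(t - cc$center_s)^2 / (2 * cc$width_s^2)) *
      cos(2 * pi * cc$freq_hz * (t - cc$center_s))
  }
  # cosine edge taper keeps the template support strictly inside the window
  edge <- 0.08 * fs
  w <- rep(1, length(t))
  ramp_in <- seq_len(round(edge))
  w[ramp_in] <- 0.5 * (1 - cos(pi * (ramp_in - 1) / edge))
  w[length(t) + 1 - ramp_in] <- w[ramp_in]
  h <- h * w
  h <- h / max(abs(h)) * params$bcg_amp
  list(waveform = h, pre = pre, post = post)
}

#' Simulate the ballistocardiogram (BCG) artifact
#'
#' Places a smooth per-beat template (support <= 0.7 s, power concentrated
#' below 25 Hz, peak > 50 uV at default parameters) at every R peak, shifted
#' by the pulse-arrival delay, with per-beat amplitude and latency jitter.
#' Overlapping templates at short RR intervals are summed.
#'
#' @param rpeaks Sorted 0-based R-peak samples.
#' @param params An [artifact_params()] object.
#' @param fs Sampling rate (Hz).
#' @param n_samples Output length in samples.
#' @param topography Per-channel coupling gains.
#' @param seed Integer seed for the beat jitter.
#' @return channels x samples matrix with attribute `"source"`.
#' @export
simulate_bcg <- function(rpeaks, params, fs, n_samples, topography, seed = 1L) {
  source <- numeric(n_samples)
  if (length(rpeaks) > 0) {
    if (is.unsorted(rpeaks)) abort("rpeaks must be sorted.")
    tmpl <- bcg_template(params, fs)
    len <- length(tmpl$waveform)
    with_local_seed(seed, {
      amp <- pmax(0.1, rnorm(length(rpeaks), 1, params$beat_amp_cv))
      lat <- round(rnorm(length(rpeaks), 0, params$beat_latency_sd_ms / 1000 * fs))
      if (params$beat_amp_cv == 0) amp <- rep(1, length(rpeaks))
      if (params$beat_latency_sd_ms == 0) lat <- rep(0L, length(rpeaks))
      anchors <- rpeaks + round(params$bcg_delay_s * fs) + lat
      for (i in seq_along(anchors)) {
        a <- anchors[i] - tmpl$pre + 1L  # 1-based start
        idx <- a:(a + len - 1L)
        keep <- idx >= 1L & idx <= n_samples
        source[idx[keep]] <- source[idx[keep]] + amp[i] * tmpl$waveform[keep]
      }
    })
  }
  out <- outer(as.numeric(topography), source)
  attr(out, "source") <- source
  out
}

#' Simulate the helium-pump vibration artifact
#'
#' A stationary sum of pump-fundamental harmonics (fundamental >= 30 Hz) with
#' slow random amplitude modulation, scaled to `params$pump_amp` RMS on a
#' gain-1 channel.
#'
#' @param params An [artifact_params()] object.
#' @param fs Sampling rate (Hz).
#' @param duration_s Duration (s).
#' @param gains Per-channel coupling gains.
#' @param seed Integer seed for the amplitude modulation.
#' @return channels x samples matrix with attribute `"source"`.
#' @export
simulate_pump <- function(params, fs, duration_s, gains, seed = 1L) {
  if (params$pump_f0_hz < 30) abort("pump fundamental must be >= 30 Hz.")
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs
  src <- numeric(n)
  for (k in seq_len(params$pump_harmonics)) {
    f <- k * params$pump_f0_hz
    if (f >= fs / 2) next
    src <- src + (1 / k) * cos(2 * pi * f * t + 0.9 * k)
  }
  if (any(src != 0)) src <- src / rms(src) * params$pump_amp
  src <- src * slow_am(n, fs, params$pump_am_depth, seed)
  out <- outer(as.numeric(gains), src)
  attr(out, "source") <- src
  out
}

#' Visual evoked potential kernel
#'
#' Biphasic waveform on [0, 0.5] s: a positive Gaussian peak near 120 ms and a
#' negative Gaussian peak near 175 ms, with amplitudes from [neural_params()].
#'
#' @param params A [neural_params()] object.
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of `round(0.5 * fs)` samples.
#' @export
vep_kernel <- function(params, fs) {
  t <- (0:(round(0.5 * fs) - 1)) / fs
  params$vep_p1 * exp(-(t - 0.120)^2 / (2 * 0.016^2)) +
    params$vep_n1 * exp(-(t - 0.175)^2 / (2 * 0.022^2))
}

# Event schedule for each task. Returns a tibble (condition, onset_s, kind)
# and the content duration in seconds (excluding lead-in already included in
# onsets).
task_schedule <- function(task, config, seed) {
  lead <- config$lead_in_s
  if (task == "resting") {
    onsets <- lead + (seq_len(config$n_blocks) - 1) * config$block_s
    cond <- rep(c("EO", "EC"), length.out = config$n_blocks)
    sched <- tibble::tibble(condition = cond, onset_s = onsets, kind = "block")
    list(events = sched, duration_s = lead + config$n_blocks * config$block_s + 1)
  } else if (task == "tapping") {
    with_local_seed(seed, {
      rests <- sample(c(3, 5, 7), config$n_blocks, replace = TRUE)
      onsets <- lead + 3 + cumsum(c(0, head(3 + rests, -1)))
      sched <- tibble::tibble(condition = "tap", onset_s = onsets, kind = "block")
      list(events = sched,
           duration_s = onsets[length(onsets)] + 3 + rests[length(rests)] + 1)
    })
  } else if (task == "checkerboard") {
    with_local_seed(seed, {
      cond <- sample(rep(c("LU", "LL", "RU", "RL"), config$n_trials))
      itis <- sample(c(1.7, 3.7, 5.7), length(cond), replace = TRUE)
      onsets <- lead + cumsum(c(0, head(0.7 + itis, -1)))
      sched <- tibble::tibble(condition = cond, onset_s = onsets, kind = "stimulus")
      list(events = sched, duration_s = onsets[length(onsets)] + 0.7 +
             itis[length(itis)] + 1)
    })
  } else abort(sprintf("unknown task '%s'", task))
}

#' Simulate task-locked neural activity
#'
#' Generates clean scalp EEG for one of the three evaluation tasks on top of
#' per-channel 1/f background noise:
#' \describe{
#'   \item{resting}{occipitally weighted band-limited alpha (8-12 Hz) whose
#'     amplitude alternates between eyes-open and eyes-closed blocks.}
#'   \item{tapping}{left-pericentral mu-alpha and beta oscillations attenuated
#'     by the ERD depths during 3-s tapping blocks, plus a gamma (70-80 Hz)
#'     burst in the first second of each block.}
#'   \item{checkerboard}{the [vep_kernel()] added at each stimulus onset with
#'     a topography contralateral to the stimulated hemifield.}
#' }
#'
#' @param task `"resting"`, `"tapping"` or `"checkerboard"`.
#' @param params A [neural_params()] object.
#' @param fs Sampling rate (Hz).
#' @param config A [session_config()] (for block/trial counts and lead-in).
#' @param layout A [scalp_layout()] tibble.
#' @param seed Integer seed.
#' @return List: `signal` (channels x samples matrix, uV), `events` tibble
#'   with columns `condition`, `sample`, `kind`, and `duration_s`.
#' @export
simulate_neural <- function(task, params, fs, config, layout, seed = 1L) {
  sched <- task_schedule(task, config, child_seed(seed, 101))
  n <- round(sched$duration_s * fs)
  nc <- nrow(layout)
  events <- dplyr::mutate(sched$events, sample = as.integer(round(.data$onset_s * fs)))

  sig <- matrix(0, nc, n)
  for (ch in seq_len(nc)) {
    sig[ch, ] <- pink_noise(n, fs, params$pink_level, child_seed(seed, 200 + ch))
  }

  if (task == "resting") {
    topo <- gaussian_topography(layout, c(0, -0.9), sigma = 0.45)
    env <- condition_envelope(n, fs, events,
                              on_len_s = config$block_s,
                              level = function(cond) {
                                ifelse(cond == "EC", params$alpha_ec, params$alpha_eo)
                              },
                              base_level = params$alpha_eo)
    alpha <- band_noise(n, fs, 8, 12, child_seed(seed, 301))
    sig <- sig + outer(topo, alpha * env)
  } else if (task == "tapping") {
    topo <- gaussian_topography(layout, c(-0.45, -0.1), sigma = 0.4)
    mu_env <- condition_envelope(n, fs, events, on_len_s = 3,
                                 level = function(cond) params$mu_amp * (1 - params$erd_alpha),
                                 base_level = params$mu_amp)
    beta_env <- condition_envelope(n, fs, events, on_len_s = 3,
                                   level = function(cond) params$beta_amp * (1 - params$erd_beta),
                                   base_level = params$beta_amp)
    gamma_env <- condition_envelope(n, fs, events, on_len_s = 1,
                                    level = function(cond) params$gamma_amp * (1 + params$ers_gamma),
                                    base_level = params$gamma_amp)
    mu <- band_noise(n, fs, 8, 12, child_seed(seed, 311))
    beta <- band_noise(n, fs, 15, 25, child_seed(seed, 312))
    gamma <- band_noise(n, fs, 70, 80, child_seed(seed, 313))
    sig <- sig + outer(topo, mu * mu_env + beta * beta_env + gamma * gamma_env)
  } else if (task == "checkerboard") {
    kern <- vep_kernel(params, fs)
    topo_l <- gaussian_topography(layout, c(-0.45, -0.8), sigma = 0.35)
    topo_r <- gaussian_topography(layout, c(0.45, -0.8), sigma = 0.35)
    add <- matrix(0, nc, n)
    for (i in seq_len(nrow(events))) {
      s0 <- events$sample[i] + 1L
      idx <- s0:min(s0 + length(kern) - 1L, n)
      topo <- if (events$condition[i] %in% c("LU", "LL")) topo_r else topo_l
      add[, idx] <- add[, idx] + outer(topo, kern[seq_along(idx)])
    }
    sig <- sig + add
  } else abort(sprintf("unknown task '%s'", task))

  list(signal = sig, events = events[, c("condition", "sample", "kind")],
       duration_s = sched$duration_s)
}

# amplitude envelope: base_level outside event windows, level(condition)
# inside [onset, onset + on_len_s), with 0.25-s raised-cosine transitions
condition_envelope <- function(n, fs, events, on_len_s, level, base_level) {
  env <- rep(base_level, n)
  for (i in seq_len(nrow(events))) {
    a <- events$sample[i] + 1L
    b <- min(a + round(on_len_s * fs) - 1L, n)
    if (a > n) next
    env[a:b] <- level(events$condition[i])
  }
  ramp <- round(0.25 * fs)
  if (ramp > 1) {
    k <- 0.5 * (1 - cos(2 * pi * seq_len(ramp) / (ramp + 1)))
    env <- stats::filter(c(rep(env[1], ramp), env, rep(env[n], ramp)),
                         k / sum(k), sides = 2)[(ramp + 1):(ramp + n)]
    env <- as.numeric(env)
  }
  env
}

#' Simulate the six carbon-wire loop reference channels
#'
#' Each loop is a weighted sum of lag-shifted artifact source waveforms plus
#' white sensor noise. Loops are isolated from the scalp and therefore carry
#' no neural component.
#'
#' @param sources Named list of artifact source waveforms (numeric vectors of
#'   equal length), e.g. `imaging`, `bcg`, `pump`, `motion`.
#' @param lags_ms 6 x n_sources matrix of loop-specific lags (ms, |lag| <= 50).
#' @param weights 6 x n_sources matrix of mixing weights.
#' @param noise_sd White sensor-noise SD (uV).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed for the sensor noise.
#' @return List: `loops` (6 x samples matrix), `clean` (6 x samples, noise-free
#'   mixture, the per-source decomposition summed).
#' @export
simulate_cwl_reference <- function(sources, lags_ms, weights, noise_sd = 1,
                                   fs = 5000, seed = 1L) {
  sources <- lapply(sources, as.numeric)
  n <- length(sources[[1]])
  if (any(vapply(sources, length, 1L) != n)) abort("sources must share a length.")
  lags_ms <- as.matrix(lags_ms); weights <- as.matrix(weights)
  if (nrow(lags_ms) != 6 || nrow(weights) != 6 ||
      ncol(lags_ms) != length(sources) || ncol(weights) != length(sources)) {
    abort("lags_ms and weights must be 6 x n_sources matrices.")
  }
  if (any(abs(lags_ms) > 50)) abort("loop lags must not exceed +/-50 ms.")
  clean <- matrix(0, 6, n)
  per_source <- lapply(seq_along(sources), function(s) {
    m <- matrix(0, 6, n)
    for (j in 1:6) {
      m[j, ] <- weights[j, s] * shift_series(sources[[s]], round(lags_ms[j, s] / 1000 * fs))
    }
    m
  })
  names(per_source) <- names(sources)
  for (m in per_source) clean <- clean + m
  noise <- matrix(0, 6, n)
  if (noise_sd > 0) {
    noise <- with_local_seed(seed, matrix(rnorm(6 * n, 0, noise_sd), 6, n))
  }
  list(loops = clean + noise, clean = clean, per_source = per_source, noise = noise)
}

# shift x by k samples (positive k delays the series), zero-padded
shift_series <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (k == 0) return(x)
  out <- numeric(n)
  if (k > 0) out[(k + 1):n] <- x[1:(n - k)]
  else out[1:(n + k)] <- x[(1 - k):n]
  out
}
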