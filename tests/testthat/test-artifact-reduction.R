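test_that("R-peak detection matches ground truth and is polarity-invariant", {
  fs <- 500
  dur <- 120
  n <- dur * fs
  rp <- simulate_rpeaks(dur, 65, 3, seed = 5, fs = fs)
  ecg <- simulate_ecg_trace(rp, fs, n)
  set.seed(9)
  noisy <- ecg + rnorm(n, 0, sd(ecg) / sqrt(10))   # SNR 10
  det <- detect_rpeaks(noisy, fs)
  hits <- vapply(rp, function(r) min(abs(det - r)) <= 0.010 * fs, logical(1))
  expect_gte(mean(hits), 0.99)
  expect_lte(abs(length(det) - length(rp)), 2)

  flipped <- detect_rpeaks(-noisy, fs)
  expect_equal(length(flipped), length(det))
  expect_lte(mean(abs(flipped - det)), 2)

  expect_warning(none <- detect_rpeaks(numeric(5000), fs), "flat")
  expect_length(none, 0)
  expect_true(all(diff(det) >= 0.3 * fs))
})

test_that("AAS removes a stationary periodic artifact to numerical zero", {
  fs <- 500
  ap <- artifact_params()
  img <- simulate_imaging_artifact(ap, fs, 22, gains = c(1, 0.5))[, 1:11000]
  rec <- new_recording(img, fs, c("A", "B"))
  vols <- seq(0, 11000 - 550, by = 550)
  out <- aas_correct(rec, vols, n_windows = 10, span = c(0L, 550L))
  interior <- 2751:8250
  expect_lt(rms(out$recording$data[, interior]) / rms(rec$data[, interior]),
            1e-8)

  # a single averaging window degenerates to exact self-subtraction
  o1 <- aas_correct(rec, vols, n_windows = 1, span = c(0L, 550L))
  expect_lt(max(abs(o1$recording$data)) / max(abs(rec$data)), 1e-12)

  expect_error(aas_correct(rec, vols[1:5], n_windows = 25, span = c(0L, 550L)),
               "reduce n_windows")
})

test_that("imaging-artifact AAS attenuates slice harmonics by > 30 dB", {
  session <- assemble_session(tiny_session_config(seed = 12))
  rec <- session$recording
  iar <- run_variant(rec, session$markers, "IAR")
  i <- channels_with_role(rec, "scalp")[1]
  before <- welch_psd(rec$data[i, ], rec$fs, nperseg = 8192)
  after <- welch_psd(iar$data[i, ], rec$fs, nperseg = 8192)
  f_slice <- 16 / 1.1
  for (k in 1:3) {
    bin <- which.min(abs(before$freqs - k * f_slice))
    drop <- before$power[1, bin] - after$power[1, bin]
    expect_gt(drop, 30)
  }
})

test_that("OBS residuals are orthogonal to the fitted basis and small", {
  fs <- 500
  dur <- 120
  n <- dur * fs
  ap <- artifact_params(beat_amp_cv = 0.2, beat_latency_sd_ms = 0)
  rp <- simulate_rpeaks(dur, 65, 3, seed = 5, fs = fs)
  bcg <- simulate_bcg(rp, ap, fs, n, topography = c(1, 0.8), seed = 6)
  rec <- new_recording(bcg[, ], fs, c("A", "B"))
  anchors <- rp + round(0.21 * fs)
  span <- round(c(0.25, 0.65) * fs)
  out <- obs_correct(rec, anchors, n_pcs = 3, span = span)

  # amplitude-jittered BCG with no neural signal: residual under 10%
  expect_lt(rms(out$recording$data) / rms(rec$data), 0.10)

  # normal equations: residual epochs orthogonal to [mean, PCs]
  B <- cbind(out$basis[[1]]$mean, out$basis[[1]]$components)
  for (i in seq(5, length(out$anchors_used) - 5, by = 11)) {
    a <- out$anchors_used[i] - span[1] + 1
    res_e <- out$recording$data[1, a:(a + sum(span) - 1)]
    raw_e <- rec$data[1, a:(a + sum(span) - 1)]
    expect_lt(max(abs(crossprod(B, res_e))) /
                (sqrt(sum(raw_e^2)) * max(sqrt(colSums(B^2)))), 1e-6)
  }

  expect_error(obs_correct(rec, anchors[1:3], n_pcs = 3, span = span),
               "at least")
})

test_that("OBS with zero components reduces to mean-template subtraction", {
  fs <- 500
  n <- 60 * fs
  ap <- artifact_params(beat_amp_cv = 0, beat_latency_sd_ms = 0)
  rp <- simulate_rpeaks(60, 60, 0, seed = 2, fs = fs)
  bcg <- simulate_bcg(rp, ap, fs, n, topography = 1, seed = 3)
  rec <- new_recording(bcg, fs, "A")
  anchors <- rp + round(0.21 * fs)
  span <- round(c(0.25, 0.65) * fs)
  obs0 <- obs_correct(rec, anchors, n_pcs = 0, span = span)
  aas_all <- aas_correct(rec, anchors, n_windows = length(obs0$anchors_used),
                         span = span)
  # identical epochs: both equal the global mean template subtraction
  expect_equal(obs0$recording$data, aas_all$recording$data, tolerance = 1e-8)
})

test_that("CWL regression removes in-span lagged mixtures exactly", {
  set.seed(2)
  fs <- 500
  n <- 8000
  loops <- matrix(rnorm(6 * n), 6)
  w <- matrix(runif(12, -1, 1), 2, 6)
  lag <- c(3, -5)
  eeg <- matrix(0, 2, n)
  for (j in 1:6) {
    eeg[1, ] <- eeg[1, ] + w[1, j] * mreeg:::shift_series(loops[j, ], lag[1])
    eeg[2, ] <- eeg[2, ] + w[2, j] * mreeg:::shift_series(loops[j, ], lag[2])
  }
  rec <- new_recording(eeg, fs, c("A", "B"))
  out <- cwl_regress(rec, cwl = loops, channels = 1:2)
  expect_lt(rms(out$data) / rms(eeg), 1e-6)
})

test_that("CWL machinery with zero regressors is an exact identity", {
  set.seed(3)
  rec <- tiny_recording(2, 9000, fs = 500)
  out <- cwl_regress(rec, cwl = matrix(0, 6, 9000), channels = 1:2)
  expect_lt(max(abs(out$data - rec$data)) / rms(rec$data), 1e-10)
})

test_that("CWL regression of independent loops barely harms neural signal", {
  # per-window OLS with p regressors removes about p/W of uncorrelated
  # variance; with the default design that bounds attainable correlation
  fs <- 500
  dur <- 120
  n <- dur * fs
  ap <- artifact_params()
  rp <- simulate_rpeaks(dur, 65, 3, seed = 5, fs = fs)
  bcg <- simulate_bcg(rp, ap, fs, n, topography = 1, seed = 6)
  pump <- simulate_pump(ap, fs, dur, gains = 1, seed = 7)
  set.seed(8)
  cw <- simulate_cwl_reference(
    list(bcg = attr(bcg, "source"), pump = attr(pump, "source")),
    lags_ms = matrix(runif(12, -8, 8), 6, 2),
    weights = matrix(runif(12, 0.5, 1.5), 6, 2),
    noise_sd = 1, fs = fs, seed = 8
  )
  neural <- rbind(pink_noise(n, fs, 5, 11) + 4 * band_noise(n, fs, 8, 12, 12),
                  pink_noise(n, fs, 5, 13))
  rec <- new_recording(neural, fs, c("A", "B"))
  out <- cwl_regress(rec, cwl = cw$loops, channels = 1:2)
  r <- c(cor(out$data[1, ], neural[1, ]), cor(out$data[2, ], neural[2, ]))
  expect_true(all(r > 0.93))
  # removed variance stays near the p/W overfit bound, not far beyond it
  design <- cwl_design()
  p_over_w <- (6 * (2 * round(design$max_lag_s * fs) + 1) + 1) /
    round(design$window_s * fs)
  expect_lt(1 - min(r)^2, 3 * p_over_w)
})

test_that("correctors are linear in the input signal for fixed templates", {
  fs <- 500
  session <- assemble_session(tiny_session_config(seed = 14))
  rec <- session$recording
  vols <- marker_samples(session$markers, "volume")
  out1 <- aas_correct(rec, vols, 10, span = c(0L, 550L))$recording$data
  rec3 <- rec
  rec3$data <- rec$data * 3
  out3 <- aas_correct(rec3, vols, 10, span = c(0L, 550L))$recording$data
  expect_equal(out3, 3 * out1, tolerance = 1e-10)
})

test_that("variant composition follows the evaluation pipeline contract", {
  session <- assemble_session(tiny_session_config(seed = 15, n_blocks = 4))
  rec <- session$recording
  mk <- session$markers

  # NC is the identity
  expect_identical(run_variant(rec, mk, "NC")$data, rec$data)

  # CWL == cwl_regress(aas_correct(raw, volume markers)) exactly
  cwl_var <- run_variant(rec, mk, "CWL")
  vols <- marker_samples(mk, "volume")
  iar <- aas_correct(rec, vols, 25, span = c(0L, as.integer(round(1.1 * rec$fs))))$recording
  by_hand <- cwl_regress(iar, channels = channels_with_role(rec, "scalp"))
  expect_equal(cwl_var$data, by_hand$data, tolerance = 1e-12)

  # missing prerequisites are named
  scalp_only <- new_recording(
    rec$data[channels_with_role(rec, "scalp"), ], rec$fs,
    rec$channel_labels[channels_with_role(rec, "scalp")]
  )
  expect_error(run_variant(scalp_only, mk, "CWL"), "carbon-wire loop")
  expect_error(run_variant(scalp_only, mk, "AAS"), "ECG")
  expect_error(run_variant(rec, new_markers(), "IAR"), "volume markers")
})

test_that("BCG correction on a null artifact only mildly overcorrects", {
  # with no BCG present the principal components lock onto smooth background
  # activity, so OBS overcorrects somewhat (a known property of the method);
  # the removal must stay well below the signal scale and shrink with the
  # number of heartbeat epochs available
  cfg <- tiny_session_config(
    seed = 16, n_blocks = 4,
    artifact = artifact_params(bcg_amp = 0)
  )
  session <- assemble_session(cfg)
  iar <- run_variant(session$recording, session$markers, "IAR")
  obs <- run_variant(session$recording, session$markers, "OBS",
                     rpeaks = session$ground_truth$rpeak_samples)
  i <- channels_with_role(session$recording, "scalp")
  rel_short <- rms(obs$data[i, ] - iar$data[i, ]) / rms(iar$data[i, ])
  expect_lt(rel_short, 0.9)

  # white noise, many beats: overcorrection tracks the basis-size/beat ratio
  fs <- 500
  n <- 300 * fs
  set.seed(20)
  x <- matrix(rnorm(n), 1)
  rp <- simulate_rpeaks(300, 65, 3, seed = 2, fs = fs)
  out <- obs_correct(new_recording(x, fs, "A"), rp + round(0.21 * fs),
                     n_pcs = 3, span = round(c(0.25, 0.65) * fs))
  rel_long <- rms(out$recording$data - x) / rms(x)
  expect_lt(rel_long, 0.25)
  expect_lt(rel_long, rel_short)
})

test_that("correction quality improves in the order the evaluation reports", {
  # RMS error against the clean signal: NC > IAR > {AAS, OBS} > CWL
  wins <- 0L
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    session <- assemble_session(tiny_session_config(seed = 100 + s,
                                                    n_blocks = 4))
    v <- session_variants(session)
    i <- channels_with_role(session$recording, "scalp")
    err <- vapply(c("NC", "IAR", "AAS", "OBS", "CWL"), function(nm) {
      rms(v[[nm]]$data[i, ] - v$REF$data)
    }, numeric(1))
    ok <- err["NC"] > err["IAR"] &&
      err["IAR"] > max(err["AAS"], err["OBS"]) &&
      min(err["AAS"], err["OBS"]) > err["CWL"]
    wins <- wins + ok
  }
  expect_gte(wins, ceiling(n_seeds / 2) + 1L)
})
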