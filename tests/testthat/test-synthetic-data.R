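test_that("R-peak simulation honours rate, variability and duration limits", {
  # zero variance: beats exactly 1 s apart at 60 bpm
  rp <- simulate_rpeaks(10, 60, 0, seed = 1, fs = 500)
  expect_true(all(diff(rp) == 500L))

  # beat counts concentrate around duration * rate (CLT bound computed from
  # the generator's truncated-normal inter-beat intervals)
  counts <- vapply(1:100, function(s) {
    length(simulate_rpeaks(300, 70, 3, seed = s, fs = 100))
  }, numeric(1))
  expected <- 300 / (60 / 70)
  sd_ibi <- 60 * 3 / 70^2
  sd_count <- sd_ibi * sqrt(expected) / (60 / 70)
  expect_true(all(abs(counts - expected) < 3 * sd_count + 2))

  expect_error(simulate_rpeaks(0.1, 60, 0), "too short")
  expect_error(simulate_rpeaks(10, -5, 0), "positive")
})

test_that("imaging artifact is harmonic, TR-periodic and amplitude-scaled", {
  fs <- 500
  # single slice harmonic, no volume sidebands: a pure cosine at f_slice
  ap1 <- artifact_params(n_harmonics_slice = 1, n_harmonics_volume = 0,
                         imaging_amp = 100)
  img1 <- simulate_imaging_artifact(ap1, fs, 20, gains = 1)
  ps <- welch_psd(img1[1, ], fs, nperseg = 4096)
  expect_equal(ps$freqs[which.max(ps$power[1, ])], 16 / 1.1, tolerance = 0.01)

  # default parameters: any two consecutive TR windows identical
  ap <- artifact_params()
  img <- simulate_imaging_artifact(ap, fs, 11, gains = c(1, 0.3))
  tr <- round(1.1 * fs)
  expect_identical(img[, 1:tr], img[, (tr + 1):(2 * tr)])

  # amplitude contract
  ap2 <- artifact_params(imaging_amp = 20000)
  img2 <- simulate_imaging_artifact(ap2, fs, 3, gains = 1)
  expect_lt(abs(max(abs(img2)) - 20000) / 20000, 0.01)

  # aliasing guard
  expect_error(
    simulate_imaging_artifact(artifact_params(n_harmonics_slice = 40), 100, 2, 1),
    "Nyquist"
  )
})

test_that("BCG artifact is beat-locked, low-frequency and jitter-controlled", {
  fs <- 500
  n <- 60 * fs
  rp <- simulate_rpeaks(60, 60, 0, seed = 2, fs = fs)
  ap0 <- artifact_params(beat_amp_cv = 0, beat_latency_sd_ms = 0)
  bcg <- simulate_bcg(rp, ap0, fs, n, topography = 1, seed = 3)

  # zero jitter: every interior beat waveform identical
  tpl <- bcg_template(ap0, fs)
  a1 <- rp[3] + round(ap0$bcg_delay_s * fs)
  a2 <- rp[4] + round(ap0$bcg_delay_s * fs)
  w1 <- bcg[1, (a1 - tpl$pre + 1):(a1 + tpl$post)]
  w2 <- bcg[1, (a2 - tpl$pre + 1):(a2 + tpl$post)]
  expect_equal(w1, w2, tolerance = 1e-12)

  # default parameters put >= 90% of the power below 25 Hz
  ap <- artifact_params()
  bcg2 <- simulate_bcg(rp, ap, fs, n, topography = 1, seed = 4)
  ps <- welch_psd(attr(bcg2, "source"), fs)
  p <- 10^(ps$power[1, ] / 10)
  expect_gte(sum(p[ps$freqs <= 25]) / sum(p), 0.9)

  # peak amplitude exceeds 50 uV at defaults
  expect_gt(max(abs(bcg2)), 50)

  expect_equal(simulate_bcg(integer(), ap, fs, 100, topography = 1),
               matrix(0, 1, 100), ignore_attr = TRUE)
  expect_error(simulate_bcg(c(500, 100), ap, fs, 1000, 1), "sorted")
})

test_that("pump artifact has only pump harmonics above 30 Hz", {
  fs <- 500
  ap <- artifact_params(pump_f0_hz = 42, pump_harmonics = 2)
  pm <- simulate_pump(ap, fs, 60, gains = 1, seed = 5)
  ps <- welch_psd(attr(pm, "source"), fs, nperseg = 8192)
  p <- 10^(ps$power[1, ] / 10)
  # spectral peaks (with their AM sidebands) cluster only at 42 and 84 Hz
  big <- ps$freqs[p > max(p) * 1e-3]
  expect_true(all(abs(big - 42) < 1 | abs(big - 84) < 1))
  expect_true(any(abs(big - 84) < 1))
  expect_gte(sum(p[ps$freqs >= 30]) / sum(p), 0.99)

  expect_equal(simulate_pump(ap, fs, 1, gains = c(0, 0), seed = 1),
               matrix(0, 2, 500), ignore_attr = TRUE)
  ap_bad <- artifact_params()
  ap_bad$pump_f0_hz <- 10
  expect_error(simulate_pump(ap_bad, fs, 1, 1), ">= 30")
})

test_that("resting neural signal modulates alpha power with eye condition", {
  fs <- 500
  layout <- scalp_layout(8)
  cfg <- tiny_session_config(n_blocks = 4, block_s = 8)

  # equal EO/EC gain: band power difference vanishes
  np_null <- neural_params(alpha_eo = 10, alpha_ec = 10.0001)
  out <- simulate_neural("resting", np_null, fs, cfg, layout, seed = 11)
  occ <- which.max(gaussian_topography(layout, c(0, -0.9), 0.45))
  bp <- vapply(seq_len(nrow(out$events)), function(i) {
    a <- out$events$sample[i] + 1
    unname(band_mean_power(
      welch_psd(out$signal[occ, a:(a + 8 * fs - 1)], fs),
      band_definition("alpha")))
  }, numeric(1))
  d_null <- mean(bp[out$events$condition == "EC"]) -
    mean(bp[out$events$condition == "EO"])
  expect_lt(abs(d_null), 1)

  # defaults: EC clearly above EO
  out2 <- simulate_neural("resting", neural_params(), fs, cfg, layout, seed = 11)
  bp2 <- vapply(seq_len(nrow(out2$events)), function(i) {
    a <- out2$events$sample[i] + 1
    unname(band_mean_power(
      welch_psd(out2$signal[occ, a:(a + 8 * fs - 1)], fs),
      band_definition("alpha")))
  }, numeric(1))
  d <- mean(bp2[out2$events$condition == "EC"]) -
    mean(bp2[out2$events$condition == "EO"])
  expect_gt(d, 3)
  expect_error(simulate_neural("jumping", neural_params(), fs, cfg, layout),
               "unknown task")
})

test_that("noiseless checkerboard trials average to the VEP kernel", {
  fs <- 500
  layout <- scalp_layout(8)
  cfg <- tiny_session_config(task = "checkerboard", n_trials = 3)
  np <- neural_params(pink_level = 0)
  out <- simulate_neural("checkerboard", np, fs, cfg, layout, seed = 3)
  kern <- vep_kernel(np, fs)
  lf <- out$events$condition %in% c("LU", "LL")
  topo_r <- gaussian_topography(layout, c(0.45, -0.8), 0.35)
  ch <- which.max(topo_r)
  avg <- Reduce(`+`, lapply(out$events$sample[lf], function(s) {
    out$signal[ch, (s + 1):(s + length(kern))]
  })) / sum(lf)
  expect_equal(avg, kern * topo_r[ch], tolerance = 1e-10)
})

test_that("tapping desynchronization depth matches the power arithmetic", {
  # beta ERD depth 0.5: tap/rest amplitude ratio 0.5 -> ~ -6 dB band change
  fs <- 500
  layout <- scalp_layout(8)
  cfg <- tiny_session_config(task = "tapping", n_blocks = 8)
  np <- neural_params(pink_level = 0.01, mu_amp = 0.01, gamma_amp = 0.01,
                      beta_amp = 5, erd_beta = 0.5)
  out <- simulate_neural("tapping", np, fs, cfg, layout, seed = 4)
  ch <- which.max(gaussian_topography(layout, c(-0.45, -0.1), 0.4))
  beta <- band_definition("beta")
  dpsd <- vapply(seq_len(nrow(out$events)), function(i) {
    s <- out$events$sample[i]
    on <- unname(band_mean_power(
      welch_psd(out$signal[ch, (s + 1 + 0.25 * fs):(s + 3 * fs)], fs), beta))
    off <- unname(band_mean_power(
      welch_psd(out$signal[ch, (s - 3 * fs + 1):(s - 0.25 * fs)], fs), beta))
    on - off
  }, numeric(1))
  expect_equal(mean(dpsd), 10 * log10(0.25), tolerance = 1.2)
})

test_that("loop references are lagged artifact mixtures free of neural signal", {
  fs <- 500
  n <- 20000
  src <- list(a = rnorm(n), b = rnorm(n))
  zero <- simulate_cwl_reference(src, matrix(0, 6, 2), matrix(0, 6, 2),
                                 noise_sd = 0, fs = fs)
  expect_true(all(zero$loops == 0))

  w <- matrix(0, 6, 2); w[1, 1] <- 1
  one <- simulate_cwl_reference(src, matrix(0, 6, 2), w, noise_sd = 0, fs = fs)
  expect_equal(one$loops[1, ], src$a)

  expect_error(
    simulate_cwl_reference(src, matrix(60, 6, 2), w, 0, fs),
    "50 ms"
  )

  # loops never correlate with neural activity (they are isolated from it)
  session <- assemble_session(tiny_session_config(seed = 21))
  gt <- session$ground_truth
  i_cwl <- channels_with_role(session$recording, "cwl")
  occ_neu <- gt$neural[which.max(abs(gt$neural[, 1000])), ]
  r <- abs(cor(session$recording$data[i_cwl[1], ], occ_neu))
  expect_lt(r, 0.05)
})

test_that("assembled sessions conserve their ground-truth decomposition", {
  session <- assemble_session(tiny_session_config(seed = 33))
  gt <- session$ground_truth
  total <- Reduce(`+`, c(list(gt$neural), gt$artifacts, list(gt$noise)))
  expect_identical(session$recording$data, total)

  # CWL rows of the neural matrix are all-zero
  i_cwl <- channels_with_role(session$recording, "cwl")
  expect_true(all(gt$neural[i_cwl, ] == 0))

  # volume markers every TR
  vols <- marker_samples(session$markers, "volume")
  expect_true(all(diff(vols) == round(1.1 * 500)))

  # determinism: same seed, identical session
  session2 <- assemble_session(tiny_session_config(seed = 33))
  expect_identical(session$recording$data, session2$recording$data)
  expect_identical(session$markers, session2$markers)
  session3 <- assemble_session(tiny_session_config(seed = 34))
  expect_false(identical(session$recording$data, session3$recording$data))
})

test_that("zero-amplitude artifacts leave a clean reference-like recording", {
  cfg <- tiny_session_config(
    seed = 5,
    artifact = artifact_params(imaging_amp = 0, bcg_amp = 0, pump_amp = 0,
                               motion_amp = 0),
    cwl_noise_sd = 0.5
  )
  session <- assemble_session(cfg)
  ref <- reference_recording(session)
  i_scalp <- channels_with_role(session$recording, "scalp")
  expect_equal(session$recording$data[i_scalp, ], ref$data, ignore_attr = TRUE)
})
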