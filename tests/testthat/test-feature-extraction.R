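flat_psd <- function(level_db, fs = 500, nperseg = 4096, channels = 1) {
  nf <- nperseg %/% 2 + 1
  structure(list(
    freqs = seq(0, fs / 2, length.out = nf),
    power = matrix(level_db, channels, nf),
    channel_labels = paste0("ch", seq_len(channels)),
    params = list(nperseg = nperseg, overlap = 0.5, taper = "hamming",
                  pad = 0L, n_segments = 1L, fs = fs)
  ), class = "psd_result")
}

test_that("band power averages dB bins with inclusive edges", {
  psd <- flat_psd(-10)
  for (b in c("alpha", "beta", "gamma")) {
    expect_equal(unname(band_mean_power(psd, band_definition(b))), -10)
  }
  # bin membership arithmetic on the 500/4096 grid: k = 66..98 fall in 8-12 Hz
  n_bins <- sum(psd$freqs >= 8 & psd$freqs <= 12)
  expect_equal(n_bins, length(66:98))
  expect_error(band_mean_power(psd, 400, 500), "no frequency bins")
})

test_that("summary-channel selection standardizes, signs and orders deterministically", {
  v <- c(a = 0, b = 0, c = 0, d = 10)
  expect_equal(select_summary_channels(v, z_threshold = 1), "d")  # z = 1.5
  expect_warning(sel <- select_summary_channels(c(a = 1, b = 1, c = 1)),
                 "zero variance")
  expect_length(sel, 0)

  # sign = -1 picks the strongly negative channels
  v2 <- c(a = -10, b = 0, c = 0, d = 0)
  expect_equal(select_summary_channels(v2, 1, sign = -1), "a")

  # permutation invariance and idempotence of the resulting set
  set.seed(2)
  v3 <- stats::setNames(rnorm(12), letters[1:12])
  s1 <- select_summary_channels(v3, 1)
  s2 <- select_summary_channels(v3[sample(12)], 1)
  expect_identical(s1, s2)
  expect_identical(select_summary_channels(v3, 1), s1)
})

test_that("summary PSDs are dB-domain means over selected channels", {
  psd <- flat_psd(-10, channels = 2)
  psd$power[2, ] <- -20
  one <- summary_channel_psd(psd, "ch1")
  expect_equal(unname(one$power[1, 1]), -10)
  both <- summary_channel_psd(psd, c("ch1", "ch2"))
  expect_equal(unname(both$power[1, 1]), -15)     # dB-domain convention
  expect_error(summary_channel_psd(psd, "nope"), "unknown channel")
})

test_that("contra/ipsi difference waves behave under symmetry and label swaps", {
  fs <- 100
  n <- 70
  ev <- tibble::tibble(condition = c("LU", "LL", "RU", "RL"),
                       sample = c(100, 300, 500, 700), kind = "stimulus")
  kern <- sin(seq(0, pi, length.out = n))
  mk_rec <- function(gain_left, gain_right) {
    data <- matrix(0, 2, 1000)
    for (i in seq_len(nrow(ev))) {
      idx <- (ev$sample[i] + 1):(ev$sample[i] + n)
      contra_right <- ev$condition[i] %in% c("LU", "LL")
      data[1, idx] <- data[1, idx] + kern * (if (contra_right) 0.2 else gain_left)
      data[2, idx] <- data[2, idx] + kern * (if (contra_right) gain_right else 0.2)
    }
    new_recording(data, fs, c("L1", "R1"))
  }
  hemi <- list(left = "L1", right = "R1")
  rec <- mk_rec(1, 1)
  ep <- epoch_data(rec, ev, 0, 0.7)
  w <- contra_ipsi_waves(ep, hemi)
  expect_equal(max(abs(w$contra - kern * 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(w$ipsi - kern * 0.2)), 0, tolerance = 1e-12)

  # identical hemispheres: difference is identically zero
  sym <- mk_rec(0.2, 0.2)
  w0 <- contra_ipsi_waves(epoch_data(sym, ev, 0, 0.7), hemi)
  expect_true(all(abs(w0$difference) < 1e-12))

  # swapping the hemisphere labels negates the difference wave
  ws <- contra_ipsi_waves(ep, list(left = "R1", right = "L1"))
  expect_equal(ws$difference, -w$difference)

  ev_bad <- ev[1:2, ]
  expect_error(contra_ipsi_waves(epoch_data(rec, ev_bad, 0, 0.7), hemi),
               "quadrant conditions")
})

test_that("window mean amplitudes use closed windows at ms resolution", {
  fs <- 1000
  x <- rep(3, 500)
  expect_equal(window_mean_amplitude(x, c(100, 140), fs, t0_s = 0), 3)
  ramp <- seq(0, 1, length.out = 500)
  m <- window_mean_amplitude(ramp, c(0, 499), fs, t0_s = 0)
  expect_equal(m, 0.5, tolerance = 1 / 500)
  expect_error(window_mean_amplitude(x, c(400, 600), fs, 0), "outside the epoch")
})

test_that("RMS-ratio SNR is scale-invariant and rewards averaging", {
  fs <- 500
  t0 <- -0.2
  nt <- round(0.7 * fs)
  tt <- t0 + (seq_len(nt) - 1) / fs
  kern <- 5 * exp(-(tt - 0.12)^2 / (2 * 0.016^2))
  set.seed(11)
  mk_trial <- function() kern + rnorm(nt, 0, 2)
  x <- mk_trial()
  expect_equal(snr_rms(3 * x, c(100, 140), c(-200, 0), fs, t0),
               snr_rms(x, c(100, 140), c(-200, 0), fs, t0))

  # averaging time-locked trials raises SNR (trial level vs average level)
  snr_t <- mean(replicate(40, snr_rms(mk_trial(), c(100, 140), c(-200, 0), fs, t0)))
  erp <- rowMeans(replicate(40, mk_trial()))
  snr_a <- snr_rms(erp, c(100, 140), c(-200, 0), fs, t0)
  expect_gt(snr_a, snr_t)

  expect_error(snr_rms(numeric(nt), c(100, 140), c(-200, 0), fs, t0),
               "baseline RMS is zero")
})

test_that("averaging n equal-variance channels attenuates noise RMS by sqrt(n)", {
  set.seed(13)
  noise <- matrix(rnorm(30 * 20000), 30)
  f8 <- rms(noise[1, ]) / rms(colMeans(noise[1:8, ]))
  f30 <- rms(noise[1, ]) / rms(colMeans(noise))
  expect_equal(f8, sqrt(8), tolerance = 0.05)
  expect_equal(f30, sqrt(30), tolerance = 0.05)
})

test_that("rmsd satisfies its defining identities", {
  a <- c(1, 2, 3, 4)
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, a + 2), 2)
  # orthogonal unit-RMS series differ by sqrt(2)
  n <- 1000
  u <- sin(2 * pi * 5 * (1:n) / n); u <- u / rms(u)
  v <- cos(2 * pi * 5 * (1:n) / n); v <- v / rms(v)
  expect_equal(rmsd(u, v), sqrt(2), tolerance = 1e-6)
  expect_error(rmsd(1:3, 1:4), "lengths differ")
})
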