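# Seeded noise sources shared by the simulator. All functions restore the
# caller's RNG state, so session generation is reproducible from one seed
# without disturbing the global stream.

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# child seed derived from a parent seed; kept below 2^31
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

#' 1/f (pink) background noise
#'
#' Spectral-shaping generator: white Gaussian noise is filtered in the
#' frequency domain with a 1/sqrt(f) amplitude profile and rescaled to the
#' requested RMS.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param rms_uv Target RMS in microvolts.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, rms_uv = 1, seed = 1L) {
  if (rms_uv == 0) return(numeric(n))
  with_local_seed(seed, {
    w <- rnorm(n)
    f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
    f[f > fs / 2] <- fs - f[f > fs / 2]  # mirror to two-sided frequencies
    gain <- ifelse(f > 0, 1 / sqrt(pmax(f, 1 / n)), 0)
    x <- Re(fft(fft(w) * gain, inverse = TRUE)) / n
    x * rms_uv / rms(x)
  })
}

# white noise band-limited to [lo, hi] Hz by a frequency-domain brick mask,
# rescaled to unit RMS; used as the carrier of simulated oscillations
band_noise <- function(n, fs, lo, hi, seed) {
  with_local_seed(seed, {
    w <- rnorm(n)
    f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
    f[f > fs / 2] <- fs - f[f > fs / 2]
    mask <- as.numeric(f >= lo & f <= hi)
    x <- Re(fft(fft(w) * mask, inverse = TRUE)) / n
    x / rms(x)
  })
}

# slow amplitude-modulation track in [1-depth, 1+depth]: heavily smoothed
# uniform noise interpolated to n samples
slow_am <- function(n, fs, depth, seed, bw_hz = 0.2) {
  if (depth == 0) return(rep(1, n))
  with_local_seed(seed, {
    k <- max(4L, ceiling(n / fs * bw_hz) + 2L)
    knots <- runif(k, -1, 1)
    m <- stats::spline(seq(0, 1, length.out = k), knots,
                       xout = seq(0, 1, length.out = n))$y
    m <- m / max(abs(m), 1e-12)
    1 + depth * m
  })
}
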