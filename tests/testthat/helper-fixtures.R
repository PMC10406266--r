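# Small fixtures shared across the suite. Everything is generated in code;
# sizes are kept desk-scale so single tests stay in the seconds range.

# a compact session: 8 scalp channels, 500 Hz, ~40 s
tiny_session_config <- function(task = "resting", seed = 7L, n_blocks = 4,
                                block_s = 8, n_trials = 4, n_channels = 8,
                                ...) {
  session_config(
    task = task, seed = seed, fs_hz = 500, tr_s = 1.1,
    n_channels = n_channels, n_blocks = n_blocks, block_s = block_s,
    n_trials = n_trials, lead_in_s = 2, ...
  )
}

# a tiny recording with known content
tiny_recording <- function(n_chan = 3, n = 200, fs = 100, seed = 1) {
  set.seed(seed)
  new_recording(matrix(rnorm(n_chan * n), n_chan), fs,
                paste0("ch", seq_len(n_chan)))
}

# draw a dataset from the two-level model's own generative process
gen_two_level <- function(seed, J = 8, nb = 20, beta = c(1, 0.8),
                          tau = c(0.5, 0.4), rho = 0.3, sigma = 1) {
  set.seed(seed)
  x <- runif(J * nb, -1, 1)
  pid <- rep(seq_len(J), each = nb)
  S <- matrix(c(tau[1]^2, rho * prod(tau), rho * prod(tau), tau[2]^2), 2)
  bp <- t(chol(S)) %*% matrix(rnorm(2 * J), 2) + beta
  y <- bp[1, pid] + bp[2, pid] * x + rnorm(J * nb, 0, sigma)
  list(spec = model_spec(y, cbind(intercept = 1, slope = x), pid,
                         resid_structure = "single"),
       beta = beta, bp = bp)
}
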