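#' MCMC convergence diagnostics
#'
#' Rank-normalized split potential-scale-reduction (R-hat), bulk and tail
#' effective sample sizes and the Monte Carlo standard error of the mean,
#' computed per parameter. Chains are split in half; draws are rank-
#' normalized through the inverse normal transform; R-hat is the maximum of
#' the rank-normalized and folded (median-absolute-deviation) statistics;
#' bulk ESS is the effective size of the rank-normalized draws and tail ESS
#' the smaller of the effective sizes of the 5% and 95% quantile indicator
#' series. Parameters that are constant across all draws have undefined
#' diagnostics and are reported as `NA`.
#'
#' @param samples A `posterior_draws` object (or an iterations x chains x
#'   parameters array).
#' @return Tibble with columns `parameter`, `rhat`, `ess_bulk`, `ess_tail`,
#'   `mcse`.
#' @export
compute_diagnostics <- function(samples) {
  arr <- if (inherits(samples, "posterior_draws")) samples$draws else samples
  if (length(dim(arr)) != 3) abort("draws must be iterations x chains x parameters.")
  if (dim(arr)[2] < 2) abort("diagnostics require at least 2 chains.")
  if (dim(arr)[1] < 4) abort("diagnostics require at least 4 draws per chain.")
  pars <- dimnames(arr)[[3]] %||% paste0("par", seq_len(dim(arr)[3]))
  out <- lapply(seq_len(dim(arr)[3]), function(k) {
    x <- arr[, , k, drop = FALSE]
    dim(x) <- dim(arr)[1:2]
    tibble::tibble(
      parameter = pars[k],
      rhat = rhat_rank(x),
      ess_bulk = ess_bulk(x),
      ess_tail = ess_tail(x),
      mcse = mcse_mean(x)
    )
  })
  dplyr::bind_rows(out)
}

split_chains <- function(x) {
  n <- nrow(x)
  h <- n %/% 2
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  s <- length(x)
  z <- qnorm((rank(x, ties.method = "average") - 3 / 8) / (s + 1 / 4))
  array(z, dim = dim(x))
}

rhat_basic <- function(x) {
  # x: draws x chains, already split
  n <- nrow(x); m <- ncol(x)
  cm <- colMeans(x)
  w <- mean(apply(x, 2, var))
  b <- n * var(cm)
  vp <- (n - 1) / n * w + b / n
  if (w < 1e-300) return(NA_real_)
  sqrt(vp / w)
}

rhat_rank <- function(x) {
  if (all(x == x[1])) return(NA_real_)
  xs <- split_chains(x)
  bulk <- rhat_basic(rank_normalize(xs))
  folded <- rhat_basic(rank_normalize(abs(xs - median(xs))))
  max(bulk, folded)
}

ess_basic <- function(x) {
  # x: draws x chains, already split; Geyer initial monotone sequence
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  chain_var <- apply(x, 2, var)
  w <- mean(chain_var)
  if (w < 1e-300) return(NA_real_)
  b <- n * var(colMeans(x))
  vp <- (n - 1) / n * w + b / n
  ac <- vapply(seq_len(m), function(j) {
    xc <- x[, j] - mean(x[, j])
    if (sum(xc^2) < 1e-300) return(numeric(n))
    v <- fft(c(xc, numeric(2^ceiling(log2(2 * n)) - n)))
    a <- Re(fft(v * Conj(v), inverse = TRUE))[seq_len(n)]
    a / a[1] * (sum(xc^2) / n)
  }, numeric(n))
  mean_ac <- rowMeans(ac)
  rho <- 1 - (w - mean_ac) / vp
  # paired sums, truncated at the first negative pair, monotone-decreasing
  maxp <- (n - 1) %/% 2
  tau <- 0
  prev <- Inf
  for (k in 0:maxp) {
    p <- rho[2 * k + 1] + if (2 * k + 2 <= n) rho[2 * k + 2] else 0
    if (k > 0 && p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + p
  }
  tau <- max(2 * tau - 1, 1 / log10(n * m + 1), 1e-8)
  min(n * m / tau, n * m * log10(n * m))
}

ess_bulk <- function(x) {
  if (all(x == x[1])) return(NA_real_)
  ess_basic(rank_normalize(split_chains(x)))
}

ess_tail <- function(x) {
  if (all(x == x[1])) return(NA_real_)
  xs <- split_chains(x)
  q <- quantile(xs, c(0.05, 0.95), names = FALSE)
  e1 <- ess_basic(rank_normalize(array(as.numeric(xs <= q[1]), dim = dim(xs))))
  e2 <- ess_basic(rank_normalize(array(as.numeric(xs <= q[2]), dim = dim(xs))))
  min(e1, e2)
}

mcse_mean <- function(x) {
  e <- ess_basic(split_chains(x))
  if (is.na(e)) return(NA_real_)
  sd(x) / sqrt(e)
}
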