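#' Optimal basis set (OBS) BCG correction
#'
#' Per channel, heartbeat epochs (constant length, anchored at the delayed R
#' peaks) are stacked and the epoch mean plus the first `n_pcs` principal
#' components of the stack form a basis that is least-squares fitted to, and
#' subtracted from, every epoch. Residuals are orthogonal to the fitted basis
#' by construction. Overlapping epochs are resolved by nearest-anchor
#' ownership. If the epoch stack cannot support `n_pcs` components the count
#' is reduced with a warning.
#'
#' @param rec An [new_recording()] object.
#' @param anchors Sorted 0-based anchor samples (delayed R peaks).
#' @param n_pcs Number of principal components in the basis (default 3).
#' @param span Epoch span `c(pre, post)` in samples (see [aas_correct()]).
#' @param channels Channels to correct (default: all).
#' @return List: `recording` (corrected), `anchors_used`, `basis` (per-channel
#'   list with `mean` and `components`, component waveforms orthonormal).
#' @export
obs_correct <- function(rec, anchors, n_pcs = 3, span,
                        channels = seq_len(nrow(rec$data))) {
  anchors <- sort(as.integer(anchors))
  pre <- span[1]; post <- span[2]
  len <- pre + post
  n <- n_samples(rec)
  fit <- anchors - pre >= 0 & anchors + post <= n
  anchors <- anchors[fit]
  na <- length(anchors)
  if (na < n_pcs + 2) {
    abort(sprintf("Need at least n_pcs + 2 = %d heartbeat epochs, have %d.",
                  n_pcs + 2, na))
  }
  own <- ownership_ranges(anchors, pre, post, n)
  starts <- anchors - pre + 1L
  data <- rec$data
  basis_out <- vector("list", length(channels))
  names(basis_out) <- rec$channel_labels[channels]

  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    x <- rec$data[ch, ]
    epochs <- matrix(0, na, len)
    for (i in seq_len(na)) {
      epochs[i, ] <- x[starts[i]:(starts[i] + len - 1L)]
    }
    m <- colMeans(epochs)
    k <- n_pcs
    comps <- NULL
    if (k > 0) {
      centered <- sweep(epochs, 2, m)
      sv <- svd(centered, nu = 0, nv = min(k, len))
      rank <- sum(sv$d > max(sv$d[1], 1e-12) * 1e-10)
      if (rank < k) {
        warn(sprintf("channel %s: epoch matrix rank %d < %d components; reducing.",
                     rec$channel_labels[ch], rank, k))
        k <- rank
      }
      if (k > 0) comps <- sv$v[, seq_len(k), drop = FALSE]  # orthonormal
    }
    B <- cbind(m, comps)
    # least-squares fit of the basis to every epoch, then subtract
    coefs <- qr.solve(B, t(epochs))           # (k+1) x na
    fitted <- t(B %*% coefs)                  # na x len
    for (i in seq_len(na)) {
      a <- own$lo[i]; b <- own$hi[i]
      if (a > b) next
      rel <- (a - starts[i] + 1L):(b - starts[i] + 1L)
      data[ch, a:b] <- data[ch, a:b] - fitted[i, rel]
    }
    basis_out[[ci]] <- list(mean = m, components = comps)
  }
  list(
    recording = new_recording(data, rec$fs, rec$channel_labels,
                              rec$channel_roles, rec$reference),
    anchors_used = anchors,
    basis = basis_out
  )
}
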