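#' Average artifact subtraction (AAS)
#'
#' The classic sliding-template correction for periodic MR artifacts. For
#' each anchor marker (volume onsets for the imaging artifact, delayed R
#' peaks for the BCG artifact) the channel-wise mean over the `n_windows`
#' nearest epochs (a centered sliding window over anchors, truncated at the
#' recording edges) is subtracted from that anchor's epoch. Samples outside
#' all epochs are untouched. When epochs overlap (short RR intervals), each
#' sample is corrected by its nearest anchor.
#'
#' @param rec An [new_recording()] object.
#' @param anchors Sorted 0-based anchor samples.
#' @param n_windows Number of epochs averaged per template (25 for imaging
#'   artifact reduction, 21 for BCG correction).
#' @param span Epoch span `c(pre, post)` in samples relative to the anchor:
#'   the epoch covers `[anchor - pre, anchor + post)`.
#' @param channels Indices of channels to correct (default: all).
#' @param keep_templates Return the per-anchor templates (may be large).
#' @return List: `recording` (corrected), `anchors_used`, and `templates`
#'   (channels x anchors x span array) if requested.
#' @export
aas_correct <- function(rec, anchors, n_windows = 25, span,
                        channels = seq_len(nrow(rec$data)),
                        keep_templates = FALSE) {
  anchors <- sort(as.integer(anchors))
  pre <- span[1]; post <- span[2]
  len <- pre + post
  n <- n_samples(rec)
  fit <- anchors - pre >= 0 & anchors + post <= n
  if (any(!fit)) {
    log_msg("info", sprintf("dropping %d anchor(s) whose epochs leave the recording",
                            sum(!fit)))
    anchors <- anchors[fit]
  }
  na <- length(anchors)
  if (na < n_windows) {
    abort(sprintf(
      "Only %d usable anchors for %d averaging windows; reduce n_windows.",
      na, n_windows
    ))
  }

  # centered sliding window over anchor index, truncated at the edges
  half <- (n_windows - 1) %/% 2
  w_start <- pmin(pmax(seq_len(na) - half, 1L), na - n_windows + 1L)
  w_end <- w_start + n_windows - 1L

  own <- ownership_ranges(anchors, pre, post, n)
  data <- rec$data
  templates <- if (keep_templates) {
    array(NA_real_, dim = c(length(channels), na, len))
  } else NULL

  starts <- anchors - pre + 1L  # 1-based epoch starts
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    x <- rec$data[ch, ]
    epochs <- matrix(0, na, len)
    for (i in seq_len(na)) {
      epochs[i, ] <- x[starts[i]:(starts[i] + len - 1L)]
    }
    cs <- rbind(0, apply(epochs, 2, cumsum))
    tmpl <- (cs[w_end + 1L, , drop = FALSE] - cs[w_start, , drop = FALSE]) / n_windows
    if (keep_templates) templates[ci, , ] <- tmpl
    for (i in seq_len(na)) {
      a <- own$lo[i]; b <- own$hi[i]
      if (a > b) next
      rel <- (a - starts[i] + 1L):(b - starts[i] + 1L)
      data[ch, a:b] <- data[ch, a:b] - tmpl[i, rel]
    }
  }
  out <- list(
    recording = new_recording(data, rec$fs, rec$channel_labels,
                              rec$channel_roles, rec$reference),
    anchors_used = anchors
  )
  if (keep_templates) out$templates <- templates
  out
}

# 1-based inclusive sample ranges owned by each anchor: full epochs where
# they do not overlap; overlapping stretches are split at the overlap
# midpoint so each sample is corrected by its nearest anchor
ownership_ranges <- function(anchors, pre, post, n) {
  na <- length(anchors)
  lo <- anchors - pre + 1L
  hi <- anchors + post             # inclusive 1-based end
  if (na > 1) {
    for (i in seq_len(na - 1)) {
      if (hi[i] >= lo[i + 1]) {
        cut <- (hi[i] + lo[i + 1]) %/% 2L
        hi[i] <- cut
        lo[i + 1] <- cut + 1L
      }
    }
  }
  list(lo = as.integer(pmax(lo, 1L)), hi = as.integer(pmin(hi, n)))
}
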