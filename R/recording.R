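#' Multichannel EEG recording container
#'
#' An `eeg_recording` stores a channels-by-samples amplitude matrix in
#' microvolts together with the sampling rate, channel labels, channel roles
#' and the reference state. Roles distinguish scalp electrodes from the six
#' carbon-wire loop (CWL) reference channels and the single ECG channel; all
#' corrections and spectral analyses act on scalp channels only unless a
#' function documents otherwise.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique labels, one per row.
#' @param channel_roles Character vector, each one of `"scalp"`, `"cwl"`,
#'   `"ecg"`. Defaults to all-scalp.
#' @param reference Reference description: a channel label or `"average"`.
#' @return An object of class `eeg_recording`.
#' @seealso [validate_recording()], [read_brainvision()], [write_brainvision()]
#' @export
new_recording <- function(data, fs, channel_labels,
                          channel_roles = rep("scalp", nrow(data)),
                          reference = "FCz") {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.")
  }
  rec <- structure(
    list(
      data = data,
      fs = as.numeric(fs),
      channel_labels = as.character(channel_labels),
      channel_roles = as.character(channel_roles),
      reference = reference
    ),
    class = "eeg_recording"
  )
  problems <- validate_recording(rec)
  if (length(problems) > 0) {
    abort(c("Invalid recording:", problems))
  }
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  roles <- table(factor(x$channel_roles, levels = c("scalp", "cwl", "ecg")))
  cat(sprintf(
    "<eeg_recording> %d channels (%d scalp, %d cwl, %d ecg) x %d samples @ %g Hz (%.1f s), ref: %s\n",
    nrow(x$data), roles[["scalp"]], roles[["cwl"]], roles[["ecg"]],
    ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference
  ))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param rec An [new_recording()] object.
#' @return `n_samples()`: integer sample count; `duration()`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration <- function(rec) ncol(rec$data) / rec$fs

#' Indices of channels with a given role
#' @param rec An [new_recording()] object.
#' @param role `"scalp"`, `"cwl"` or `"ecg"`.
#' @return Integer vector of row indices.
#' @export
channels_with_role <- function(rec, role) which(rec$channel_roles == role)

#' Validate a recording against its structural invariants
#'
#' Checks the container invariants: unique labels, positive sampling rate,
#' matching dimensions, finite amplitudes, and role counts (0 or 6 CWL loops,
#' 0 or 1 ECG channel). Reports rather than raises so callers can decide.
#'
#' @param rec An [new_recording()]-shaped list.
#' @return Character vector of violations; empty if the recording is valid.
#' @export
validate_recording <- function(rec) {
  problems <- character()
  if (!is.matrix(rec$data) || !is.numeric(rec$data)) {
    return("data is not a numeric matrix")
  }
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || !is.finite(rec$fs) || rec$fs <= 0) {
    problems <- c(problems, sprintf("sampling rate must be a positive number, got %s",
                                    format(rec$fs)))
  }
  if (length(rec$channel_labels) != nrow(rec$data)) {
    problems <- c(problems, sprintf(
      "data has %d rows but %d channel labels", nrow(rec$data), length(rec$channel_labels)
    ))
  }
  dup <- unique(rec$channel_labels[duplicated(rec$channel_labels)])
  if (length(dup) > 0) {
    problems <- c(problems, sprintf("duplicate channel label(s): %s",
                                    paste(dup, collapse = ", ")))
  }
  if (length(rec$channel_roles) != nrow(rec$data)) {
    problems <- c(problems, "one role per channel is required")
  }
  bad_roles <- setdiff(unique(rec$channel_roles), c("scalp", "cwl", "ecg"))
  if (length(bad_roles) > 0) {
    problems <- c(problems, sprintf("unknown channel role(s): %s",
                                    paste(bad_roles, collapse = ", ")))
  }
  n_cwl <- sum(rec$channel_roles == "cwl")
  if (!n_cwl %in% c(0L, 6L)) {
    problems <- c(problems, sprintf("cwl channel count must be 0 or 6, got %d", n_cwl))
  }
  n_ecg <- sum(rec$channel_roles == "ecg")
  if (!n_ecg %in% c(0L, 1L)) {
    problems <- c(problems, sprintf("ecg channel count must be 0 or 1, got %d", n_ecg))
  }
  problems
}

#' Event marker table
#'
#' Markers are stored as a tibble with columns `kind` (one of `volume`,
#' `slice`, `rpeak`, `stimulus`, `block`), `label` and `sample`. Samples are
#' 0-based; time windows throughout the package are half-open `[start, stop)`.
#'
#' @param kind Character vector of marker kinds.
#' @param label Character vector of marker labels (e.g. condition names).
#' @param sample Non-negative integer vector of 0-based sample indices.
#' @return A tibble of class `eeg_markers`, sorted by sample.
#' @export
new_markers <- function(kind = character(), label = character(), sample = integer()) {
  kinds_ok <- c("volume", "slice", "rpeak", "stimulus", "block")
  bad <- setdiff(unique(kind), kinds_ok)
  if (length(bad) > 0) {
    abort(sprintf("unknown marker kind(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(sample < 0) || any(sample != round(sample))) {
    abort("marker samples must be non-negative integers (0-based).")
  }
  out <- tibble::tibble(
    kind = as.character(kind),
    label = as.character(label),
    sample = as.integer(round(sample))
  )
  out <- dplyr::arrange(out, .data$sample)
  vol <- out$sample[out$kind == "volume"]
  if (length(vol) > 1 && any(diff(vol) <= 0)) {
    abort("volume markers must be strictly increasing.")
  }
  class(out) <- c("eeg_markers", class(out))
  out
}

#' Extract marker samples of one kind
#' @param markers An [new_markers()] tibble.
#' @param kind Marker kind to keep.
#' @return Integer vector of 0-based samples.
#' @export
marker_samples <- function(markers, kind) {
  as.integer(markers$sample[markers$kind == kind])
}
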