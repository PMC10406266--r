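#' Run one artifact-correction variant
#'
#' Applies the correction pipeline that defines each evaluation variant:
#' \describe{
#'   \item{NC}{no correction (identity).}
#'   \item{IAR}{imaging artifact reduction: AAS over volume markers with 25
#'     averaging windows and TR-length epochs, applied to every channel.}
#'   \item{AAS}{IAR, then BCG correction by AAS over delayed R peaks with 21
#'     averaging windows.}
#'   \item{OBS}{IAR, then BCG correction by optimal-basis-set fitting (mean +
#'     3 principal components).}
#'   \item{CWL}{IAR, then carbon-wire loop regression.}
#' }
#' BCG-stage methods always run after IAR. R peaks are taken from `rpeaks`
#' when supplied, otherwise detected on the recording's ECG channel after IAR.
#'
#' @param rec An [new_recording()] object.
#' @param markers An [new_markers()] tibble containing volume markers (for
#'   all variants except NC).
#' @param variant One of `"NC"`, `"IAR"`, `"AAS"`, `"OBS"`, `"CWL"`.
#' @param iar_windows Averaging windows for imaging-artifact AAS (default 25).
#' @param bcg_windows Averaging windows for BCG AAS (default 21).
#' @param n_pcs Principal components for OBS (default 3).
#' @param bcg_delay_s Pulse-arrival delay from R peak to BCG epoch anchor
#'   (default 0.21 s).
#' @param bcg_span_s BCG epoch span `c(pre, post)` in seconds around the
#'   delayed anchor (default `c(0.25, 0.65)`).
#' @param design A [cwl_design()] for the CWL variant.
#' @param rpeaks Optional 0-based R-peak samples (skips ECG detection).
#' @return The corrected [new_recording()].
#' @export
run_variant <- function(rec, markers, variant = c("NC", "IAR", "AAS", "OBS", "CWL"),
                        iar_windows = 25, bcg_windows = 21, n_pcs = 3,
                        bcg_delay_s = 0.21, bcg_span_s = c(0.25, 0.65),
                        design = cwl_design(), rpeaks = NULL) {
  variant <- match.arg(variant)
  if (variant == "NC") return(rec)

  vols <- marker_samples(markers, "volume")
  if (length(vols) < 2) {
    abort(sprintf("variant %s requires volume markers; none found.", variant))
  }
  tr_samp <- as.integer(round(median(diff(vols))))
  iar <- aas_correct(rec, vols, n_windows = iar_windows,
                     span = c(0L, tr_samp))$recording
  if (variant == "IAR") return(iar)

  if (variant == "CWL") {
    if (length(channels_with_role(rec, "cwl")) != 6) {
      abort("variant CWL requires the six carbon-wire loop channels.")
    }
    return(cwl_regress(iar, design = design,
                       channels = channels_with_role(rec, "scalp")))
  }

  # AAS / OBS need R peaks
  if (is.null(rpeaks)) {
    i_ecg <- channels_with_role(rec, "ecg")
    if (length(i_ecg) != 1) {
      abort(sprintf("variant %s requires R peaks or an ECG channel.", variant))
    }
    rpeaks <- detect_rpeaks(iar$data[i_ecg, ], rec$fs)
  }
  anchors <- as.integer(round(rpeaks + bcg_delay_s * rec$fs))
  span <- as.integer(round(bcg_span_s * rec$fs))
  scalp <- channels_with_role(rec, "scalp")
  if (variant == "AAS") {
    aas_correct(iar, anchors, n_windows = bcg_windows, span = span,
                channels = scalp)$recording
  } else {
    obs_correct(iar, anchors, n_pcs = n_pcs, span = span,
                channels = scalp)$recording
  }
}

#' All evaluation variants of one session
#'
#' Convenience wrapper computing the reference signal and the five MR data
#' variants of a simulated session.
#'
#' @param session An [assemble_session()] result.
#' @param variants Character vector of variants to compute.
#' @param ... Passed to [run_variant()].
#' @return Named list of recordings, including `REF` (scalp channels only).
#' @export
session_variants <- function(session,
                             variants = c("NC", "IAR", "AAS", "OBS", "CWL"),
                             ...) {
  out <- lapply(variants, function(v) {
    run_variant(session$recording, session$markers, v, ...)
  })
  names(out) <- variants
  c(out, list(REF = reference_recording(session)))
}
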