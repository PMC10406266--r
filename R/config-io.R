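#' Write / read a session configuration as a plain-text file
#'
#' Session configurations serialize to YAML so simulated acquisitions can be
#' described, versioned and re-run outside R. Nested parameter objects
#' (artifact, neural) are stored under their own keys; the BCG template
#' component table becomes a list of rows.
#'
#' @param config A [session_config()] object.
#' @param path Output file path (conventionally `.yaml`).
#' @return `write_session_config()`: `path`, invisibly;
#'   `read_session_config()`: a [session_config()] object.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  x <- unclass(config)
  x$artifact <- unclass(x$artifact)
  x$artifact$bcg_components <- lapply(
    seq_len(nrow(config$artifact$bcg_components)),
    function(i) as.list(config$artifact$bcg_components[i, ])
  )
  x$neural <- unclass(x$neural)
  yaml::write_yaml(x, path, precision = 15)  # keep e.g. 16/1.1 Hz exact enough
  invisible(path)
}

#' @rdname write_session_config
#' @export
read_session_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$artifact$bcg_components <- do.call(rbind, lapply(x$artifact$bcg_components,
                                                     as.data.frame))
  artifact <- do.call(artifact_params, x$artifact)
  neural <- do.call(neural_params, x$neural)
  keep <- setdiff(names(x), c("artifact", "neural"))
  do.call(session_config, c(x[keep], list(artifact = artifact,
                                          neural = neural)))
}

#' Export a simulated session to disk
#'
#' Writes the recording and markers as a BrainVision triplet (via
#' [write_brainvision()]) and the ground-truth decomposition as an `.rds`
#' sidecar next to it, so any stage of the pipeline can be re-run from
#' files.
#'
#' @param session An [assemble_session()] result.
#' @param path Output directory.
#' @param basename File base name.
#' @return The header path, invisibly.
#' @export
write_session <- function(session, path, basename = "session") {
  hdr <- write_brainvision(session$recording, session$markers, path, basename)
  saveRDS(session$ground_truth,
          file.path(path, paste0(basename, "_ground_truth.rds")))
  invisible(hdr)
}

#' Export an evaluation report as delimited tables
#'
#' Writes the feature table, per-variant posterior summaries, adjacent
#' ordering probabilities, ground-truth error metrics and MCMC diagnostics
#' as tab-separated files plus a short plain-text summary.
#'
#' @param report A [run_study()] result.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(path, name),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wr(report$features, "features.tsv")
  wr(report$delta_psd, "delta_psd.tsv")
  wr(report$ordering, "ordering.tsv")
  wr(report$gt_error, "ground_truth_error.tsv")
  wr(report$diagnostics, "diagnostics.tsv")
  con <- file(file.path(path, "summary.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(path)
}
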