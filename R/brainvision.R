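#' Read a BrainVision recording
#'
#' Parses the `.vhdr`/`.vmrk`/`.eeg` triplet written by BrainVision-compatible
#' amplifiers. Only the IEEE float32 little-endian multiplexed binary dialect
#' is supported (the dialect this package writes). Amplitudes are scaled to
#' microvolts using the per-channel resolution declared in the header, and
#' marker positions are converted from the format's 1-based convention to the
#' package-wide 0-based convention.
#'
#' Channel roles have no slot in the BrainVision header; if a sidecar file
#' `<base>_channels.tsv` (written by [write_brainvision()]) is present the
#' roles and reference state are recovered from it, otherwise all channels are
#' assumed scalp.
#'
#' @param header_path Path to the `.vhdr` header file.
#' @param volume_marker Marker description treated as a volume (TR) trigger for
#'   files written by other software; default `"R128"`, the common scanner
#'   trigger label for this amplifier family.
#' @return A list with elements `recording` ([new_recording()]) and
#'   `markers` ([new_markers()]).
#' @export
read_brainvision <- function(header_path, volume_marker = "R128") {
  if (!file.exists(header_path)) {
    abort(sprintf("Header file not found: %s", header_path))
  }
  hdr <- parse_ini(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  if (is.null(ci)) abort("Malformed .vhdr: missing [Common Infos] section.")
  fmt <- bi[["BinaryFormat"]] %||% "IEEE_FLOAT_32"
  if (!identical(fmt, "IEEE_FLOAT_32")) {
    abort(sprintf("Unsupported BinaryFormat '%s' (only IEEE_FLOAT_32).", fmt))
  }
  orientation <- ci[["DataOrientation"]] %||% "MULTIPLEXED"
  if (!identical(orientation, "MULTIPLEXED")) {
    abort(sprintf("Unsupported DataOrientation '%s' (only MULTIPLEXED).", orientation))
  }
  n_chan <- as.integer(ci[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ci[["SamplingInterval"]])  # header stores microseconds

  dir <- dirname(header_path)
  eeg_path <- file.path(dir, ci[["DataFile"]])
  vmrk_path <- file.path(dir, ci[["MarkerFile"]])
  if (!file.exists(eeg_path)) abort(sprintf("Missing data file: %s", eeg_path))
  if (!file.exists(vmrk_path)) abort(sprintf("Missing marker file: %s", vmrk_path))

  ch <- hdr[["Channel Infos"]]
  labels <- character(n_chan)
  resolution <- rep(1, n_chan)
  for (i in seq_len(n_chan)) {
    entry <- ch[[sprintf("Ch%d", i)]]
    if (is.null(entry)) abort(sprintf("Malformed .vhdr: missing Ch%d entry.", i))
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resolution[i] <- as.numeric(parts[3])
  }

  raw <- readBin(eeg_path, what = "numeric", size = 4L, endian = "little",
                 n = file.size(eeg_path) / 4L)
  if (length(raw) %% n_chan != 0) {
    abort(sprintf(
      "Binary stream length (%d values) is not a multiple of the declared %d channels.",
      length(raw), n_chan
    ))
  }
  data <- matrix(raw, nrow = n_chan) * resolution

  roles <- rep("scalp", n_chan)
  reference <- "unknown"
  sidecar <- sub("\\.vhdr$", "_channels.tsv", header_path)
  if (file.exists(sidecar)) {
    meta <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    idx <- match(labels, meta$label)
    if (!anyNA(idx)) {
      roles <- meta$role[idx]
      if ("reference" %in% names(meta)) reference <- meta$reference[1]
    }
  }

  markers <- parse_vmrk(readLines(vmrk_path, warn = FALSE), volume_marker)
  rec <- new_recording(data, fs, labels, roles, reference)
  list(recording = rec, markers = markers)
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` (IEEE float32
#' little-endian, multiplexed) plus a sidecar `<base>_channels.tsv` carrying
#' channel roles and the reference state, which the standard header cannot
#' hold. Round-trips through [read_brainvision()] up to float32 quantization;
#' marker samples round-trip exactly.
#'
#' @param rec An [new_recording()] object with finite data.
#' @param markers An [new_markers()] tibble (may be empty).
#' @param path Output directory.
#' @param basename File base name (default `"recording"`).
#' @return The header path, invisibly.
#' @export
write_brainvision <- function(rec, markers = new_markers(), path,
                              basename = "recording") {
  problems <- validate_recording(rec)
  if (length(problems) > 0) abort(c("Refusing to write invalid recording:", problems))
  if (anyNA(rec$data) || !all(is.finite(rec$data))) {
    abort("Recording data contain NA or non-finite values.")
  }
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory: %s", path))
  }
  vhdr <- file.path(path, paste0(basename, ".vhdr"))
  vmrk <- file.path(path, paste0(basename, ".vmrk"))
  eeg <- file.path(path, paste0(basename, ".eeg"))
  sidecar <- file.path(path, paste0(basename, "_channels.tsv"))

  n_chan <- nrow(rec$data)
  hdr_lines <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", basename),
    sprintf("MarkerFile=%s.vmrk", basename),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", n_chan),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_chan), rec$channel_labels)
  )
  writeLines(hdr_lines, vhdr, useBytes = TRUE)

  mk_lines <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", basename),
    "",
    "[Marker Infos]"
  )
  if (nrow(markers) > 0) {
    # kind written as the marker type: BrainVision leaves the type free-form,
    # and this makes write -> read an exact identity on the marker table
    mk_lines <- c(mk_lines, sprintf(
      "Mk%d=%s,%s,%d,1,0",
      seq_len(nrow(markers)), markers$kind, markers$label, markers$sample + 1L
    ))
  }
  writeLines(mk_lines, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")

  utils::write.table(
    data.frame(label = rec$channel_labels, role = rec$channel_roles,
               reference = rec$reference),
    sidecar, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(vhdr)
}

parse_ini <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else if (!is.null(section) && grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- substr(ln, 1, eq - 1)
      out[[section]][[key]] <- substr(ln, eq + 1, nchar(ln))
    }
  }
  out
}

parse_vmrk <- function(lines, volume_marker) {
  mk <- grep("^Mk[0-9]+=", lines, value = TRUE)
  if (length(mk) == 0) return(new_markers())
  fields <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
  type <- vapply(fields, `[`, character(1), 1)
  desc <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "", character(1))
  pos <- vapply(fields, function(f) as.numeric(f[3]), numeric(1))
  keep <- !(type %in% c("New Segment")) & !is.na(pos)
  type <- type[keep]; desc <- desc[keep]; pos <- pos[keep]
  kind <- ifelse(
    tolower(type) %in% c("volume", "slice", "rpeak", "stimulus", "block"),
    tolower(type),
    ifelse(desc == volume_marker, "volume", "stimulus")
  )
  new_markers(kind = kind, label = desc, sample = pos - 1)
}
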