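#' Schematic scalp layout for the simulator
#'
#' A 32-channel subset of the 10-10 system laid out on a unit disk
#' (x: left -1 to right +1, y: occipital -1 to frontal +1). The simulator
#' needs only coarse spatial structure - occipital, pericentral and
#' parieto-occipital groupings and a left/right split - not a measured
#' montage.
#'
#' @param n_channels Number of channels (4-32); smaller counts subsample the
#'   full layout front-to-back so every scalp region stays represented.
#' @return Tibble with columns `label`, `x`, `y`, `hemisphere`
#'   (`"left"`, `"right"`, `"midline"`).
#' @export
scalp_layout <- function(n_channels = 32) {
  lab <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
           "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
           "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
           "PO7", "PO3", "PO4", "PO8", "O1", "Oz", "O2")
  x <- c(-0.31, 0.31, -0.80, -0.40, 0, 0.40, 0.80,
         -0.60, -0.20, 0.20, 0.60, -0.90, -0.45, 0, 0.45, 0.90,
         -0.60, -0.20, 0.20, 0.60, -0.80, -0.40, 0, 0.40, 0.80,
         -0.60, -0.25, 0.25, 0.60, -0.30, 0, 0.30)
  y <- c(0.90, 0.90, 0.55, 0.55, 0.55, 0.55, 0.55,
         0.30, 0.30, 0.30, 0.30, 0, 0, 0, 0, 0,
         -0.30, -0.30, -0.30, -0.30, -0.55, -0.55, -0.55, -0.55, -0.55,
         -0.80, -0.80, -0.80, -0.80, -0.95, -0.95, -0.95)
  if (n_channels < 4 || n_channels > length(lab)) {
    abort(sprintf("n_channels must be between 4 and %d.", length(lab)))
  }
  # subsample across the whole head (front to back), never a frontal prefix
  idx <- unique(round(seq(1, length(lab), length.out = n_channels)))
  xs <- x[idx]; ys <- y[idx]
  tibble::tibble(
    label = lab[idx], x = xs, y = ys,
    hemisphere = dplyr::case_when(xs < 0 ~ "left",
                                  xs > 0 ~ "right",
                                  TRUE ~ "midline")
  )
}

#' Gaussian-blob channel weights over a 2-D layout
#'
#' @param layout A [scalp_layout()] tibble.
#' @param center Length-2 numeric, blob center in layout coordinates.
#' @param sigma Blob width (layout units).
#' @param gain Peak weight.
#' @return Numeric vector of per-channel weights, one per layout row.
#' @export
gaussian_topography <- function(layout, center, sigma = 0.35, gain = 1) {
  d2 <- (layout$x - center[1])^2 + (layout$y - center[2])^2
  gain * exp(-d2 / (2 * sigma^2))
}
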