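#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rnorm runif median quantile sd var fft qnorm coef lm
#' @importFrom utils head tail
NULL

.log_env <- new.env(parent = emptyenv())
.log_env$level <- "warning"

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, quiet = 4L)

#' Control package logging verbosity
#'
#' Line-oriented logging used by the correction and pipeline functions.
#' Messages at or above the chosen level are emitted with [message()].
#'
#' @param level One of `"debug"`, `"info"`, `"warning"`, `"quiet"`.
#' @return The previous level, invisibly.
#' @export
mreeg_log_level <- function(level = c("warning", "info", "debug", "quiet")) {
  level <- match.arg(level)
  old <- .log_env$level
  .log_env$level <- level
  invisible(old)
}

log_msg <- function(level, ...) {
  if (.log_levels[[level]] >= .log_levels[[.log_env$level]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' Root-mean-square of a numeric vector or matrix
#'
#' @param x Numeric vector or matrix.
#' @return A single non-negative number.
#' @export
rms <- function(x) sqrt(mean(x^2))
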