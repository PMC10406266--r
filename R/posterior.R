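#' Pooled draws matrix of a fit
#'
#' @param samples A `posterior_draws` object.
#' @return (iterations * chains) x parameters numeric matrix.
#' @export
draws_matrix <- function(samples) {
  arr <- samples$draws
  d <- dim(arr)
  out <- matrix(arr, d[1] * d[2], d[3])
  colnames(out) <- dimnames(arr)[[3]]
  out
}

#' Posterior probability of a directed contrast
#'
#' Fraction of posterior draws satisfying an inequality. The contrast is a
#' parameter name, a numeric vector of contrast draws, or an expression
#' string combining parameter names in backticks (e.g.
#' `` "`beta[2]` - `beta[1]`" ``).
#'
#' @param samples A `posterior_draws` object (ignored when `contrast` is
#'   numeric).
#' @param contrast Parameter name, backtick expression, or draws vector.
#' @param direction `">"` (default) or `"<"`, compared against `threshold`.
#' @param threshold Comparison value (default 0).
#' @return Probability in \[0, 1\].
#' @export
posterior_probability <- function(samples, contrast, direction = c(">", "<"),
                                  threshold = 0) {
  direction <- match.arg(direction)
  if (is.numeric(contrast)) {
    v <- contrast
  } else {
    dm <- draws_matrix(samples)
    if (contrast %in% colnames(dm)) {
      v <- dm[, contrast]
    } else if (grepl("`", contrast)) {
      env <- new.env()
      for (p in colnames(dm)) assign(p, dm[, p], envir = env)
      v <- tryCatch(eval(parse(text = contrast), envir = env),
                    error = function(e) {
                      abort(sprintf("cannot resolve contrast '%s': %s",
                                    contrast, conditionMessage(e)))
                    })
    } else {
      abort(sprintf("unknown parameter '%s'", contrast))
    }
  }
  if (direction == ">") mean(v > threshold) else mean(v < threshold)
}

#' Summarize one posterior parameter
#'
#' Median and equal-tailed 66% and 95% intervals (linear-interpolation
#' quantiles), the summary convention used throughout the evaluation.
#'
#' @param samples A `posterior_draws` object or numeric draws vector.
#' @param parameter Parameter name (when `samples` is a fit).
#' @return Tibble with `median`, `l66`, `u66`, `l95`, `u95`.
#' @export
summarize_posterior <- function(samples, parameter = NULL) {
  v <- if (is.numeric(samples)) samples else {
    dm <- draws_matrix(samples)
    if (!parameter %in% colnames(dm)) {
      abort(sprintf("unknown parameter '%s'", parameter))
    }
    dm[, parameter]
  }
  q <- quantile(v, c(0.5, 0.17, 0.83, 0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(median = q[1], l66 = q[2], u66 = q[3], l95 = q[4], u95 = q[5])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a posterior fit
#'
#' One row per parameter with the posterior median, 95% interval and
#' convergence diagnostics.
#'
#' @param x A `posterior_draws` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.posterior_draws <- function(x, ...) {
  dm <- draws_matrix(x)
  sums <- purrr::map_dfr(colnames(dm), function(p) {
    s <- summarize_posterior(dm[, p])
    tibble::tibble(term = p, estimate = s$median,
                   conf.low = s$l95, conf.high = s$u95)
  })
  dplyr::left_join(sums, x$diagnostics,
                   by = c(term = "parameter"))
}

#' One-line fit summary
#'
#' @param x A `posterior_draws` object.
#' @param ... Unused.
#' @return A one-row tibble with draw counts and worst-case diagnostics.
#' @export
glance.posterior_draws <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    model = x$model,
    chains = dim(x$draws)[2],
    draws = dim(x$draws)[1] * dim(x$draws)[2],
    max_rhat = suppressWarnings(max(d$rhat, na.rm = TRUE)),
    min_ess_bulk = suppressWarnings(min(d$ess_bulk, na.rm = TRUE)),
    min_ess_tail = suppressWarnings(min(d$ess_tail, na.rm = TRUE)),
    converged = isTRUE(x$converged)
  )
}
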