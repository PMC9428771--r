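#' Point percent change between two rates
#'
#' `100 * (to / from - 1)`: the percent change implied by two
#' rate-scale values. Applied per posterior draw by
#' [cumulative_percent_change()] and [apc_series()]; exposed for
#' worked examples on published point estimates.
#'
#' @param from,to Positive rates.
#' @return Percent change (vectorized).
#' @export
percent_change <- function(from, to) {
  if (any(from <= 0)) stop("`from` must be positive", call. = FALSE)
  100 * (to / from - 1)
}

#' Round half away from zero
#'
#' Integer rounding convention used when comparing percent changes
#' with published tables (-31.38 -> -31, -34.72 -> -35).
#'
#' @param x Numeric.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

as_rate_draws <- function(draws) {
  if (!inherits(draws, "rate_draws")) {
    if (is.null(dim(draws)))
      draws <- matrix(draws, nrow = 1L)
    draws <- new_rate_draws(as.matrix(draws),
                            colnames(draws) %||% as.character(seq_len(ncol(draws))),
                            per = 1)
  }
  if (any(draws <= 0)) stop("rates must be positive", call. = FALSE)
  draws
}

#' Annual percent change series, per draw
#'
#' For every posterior draw, `APC_t = 100 * (R_t / R_{t-1} - 1)` for
#' `t = 2..n`.
#'
#' @param draws A [rate_draws()] matrix (crude or standardized rates).
#' @return A draws-by-(n-1) matrix of class `change_series` with the
#'   transition-end period labels as columns.
#' @export
apc_series <- function(draws) {
  draws <- as_rate_draws(draws)
  n <- ncol(draws)
  if (n < 2L) stop("at least 2 periods are required", call. = FALSE)
  apc <- 100 * (draws[, -1L, drop = FALSE] / draws[, -n, drop = FALSE] - 1)
  structure(apc, class = c("change_series", "matrix", "array"),
            time = attr(draws, "time")[-1L], label = attr(draws, "label"))
}

#' Cumulative percent change, per draw
#'
#' For every posterior draw, `CPC_t = 100 * (R_t / R_1 - 1)`; exactly
#' 0 at the first period. Computed per draw and then summarized, so
#' the interval is a genuine posterior interval (the posterior mean of
#' a ratio is not the ratio of posterior means).
#'
#' @param draws A [rate_draws()] matrix.
#' @param level Credible level.
#' @param ... Labels passed to [summarize_draws()].
#' @return A `rate_summary` data frame, one row per period.
#' @export
cumulative_percent_change <- function(draws, level = 0.95, ...) {
  draws <- as_rate_draws(draws)
  if (ncol(draws) < 2L) stop("at least 2 periods are required", call. = FALSE)
  cpc <- 100 * (draws / draws[, 1L] - 1)
  cpc <- new_rate_draws(cpc, attr(draws, "time"), per = 1)
  summarize_draws(cpc, level = level, quantity = "cumulative_percent_change",
                  ...)
}

#' Average annual percent change over a window, per draw
#'
#' The arithmetic mean of the per-transition annual percent changes
#' inside a contiguous window of periods, computed per posterior draw
#' and then summarized. A window of `w` consecutive periods contains
#' `w - 1` transitions; surveillance reports often use 4-year windows.
#'
#' @param draws A [rate_draws()] matrix.
#' @param window Contiguous period labels (or indices) of length >= 2.
#' @param method `"arithmetic"` (mean of APCs, default) or
#'   `"geometric"` (annualized compound change
#'   `100 * ((R_last/R_first)^(1/(w-1)) - 1)`).
#' @param level Credible level.
#' @param ... Labels passed to [summarize_draws()].
#' @return A single-row `rate_summary` data frame labeled by the
#'   window endpoints.
#' @export
aapc <- function(draws, window, method = c("arithmetic", "geometric"),
                 level = 0.95, ...) {
  method <- match.arg(method)
  draws <- as_rate_draws(draws)
  time <- attr(draws, "time")
  idx <- if (is.numeric(window)) as.integer(window) else match(as.character(window), time)
  if (anyNA(idx) || !length(idx))
    stop("window contains unknown periods", call. = FALSE)
  idx <- sort(idx)
  if (length(idx) < 2L) stop("window must span at least 2 periods", call. = FALSE)
  if (any(diff(idx) != 1L))
    stop("window must be a contiguous run of periods", call. = FALSE)
  if (idx[1] < 1L || idx[length(idx)] > ncol(draws))
    stop("window out of range", call. = FALSE)
  if (method == "arithmetic") {
    apc <- 100 * (draws[, idx[-1L], drop = FALSE] /
                    draws[, idx[-length(idx)], drop = FALSE] - 1)
    per_draw <- rowMeans(apc)
  } else {
    w <- length(idx)
    per_draw <- 100 * ((draws[, idx[w]] / draws[, idx[1L]])^(1 / (w - 1)) - 1)
  }
  out <- summarize_draws(matrix(per_draw, ncol = 1L), level = level,
                         quantity = "aapc", ...)
  out$time <- paste0(time[idx[1L]], "-", time[idx[length(idx)]])
  out
}
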