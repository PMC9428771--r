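#' Construct a surveillance case series
#'
#' A `case_series` holds evenly spaced time-series of case counts and
#' populations at risk, optionally stratified by demographic group and
#' age stratum. It is the observed-data object taken by [fit_rw()]:
#' counts `y` and populations `P` indexed by (period, group, stratum).
#'
#' @param counts Nonnegative integer array of cases, `n x k x m`
#'   (periods x groups x strata). Matrices (`n x k`) and vectors (length
#'   `n`) are promoted with singleton group/stratum dimensions.
#' @param populations Positive numeric array of populations at risk,
#'   same shape as `counts`.
#' @param time Character or integer vector of `n` period labels (for
#'   example calendar years). Integer-like labels must be strictly
#'   increasing and evenly spaced.
#' @param groups Character vector of `k` group labels.
#' @param strata Character vector of `m` age-stratum labels; use
#'   `"all"` for unstratified data.
#'
#' @return An object of class `case_series` with elements `counts`,
#'   `populations` (3-d arrays), `time`, `groups`, `strata`.
#' @export
case_series <- function(counts, populations,
                        time = NULL, groups = NULL, strata = NULL) {
  counts <- promote_array(counts)
  populations <- promote_array(populations)
  if (!identical(dim(counts), dim(populations)))
    stop("`counts` and `populations` must have identical shape", call. = FALSE)
  n <- dim(counts)[1]; k <- dim(counts)[2]; m <- dim(counts)[3]

  time <- if (is.null(time)) dimnames(counts)[[1]] else as.character(time)
  if (is.null(time)) time <- as.character(seq_len(n))
  groups <- if (is.null(groups)) dimnames(counts)[[2]] else as.character(groups)
  if (is.null(groups)) groups <- if (k == 1L) "all" else paste0("group", seq_len(k))
  strata <- if (is.null(strata)) dimnames(counts)[[3]] else as.character(strata)
  if (is.null(strata)) strata <- if (m == 1L) "all" else paste0("stratum", seq_len(m))

  if (length(time) != n || length(groups) != k || length(strata) != m)
    stop("label lengths do not match array dimensions", call. = FALSE)
  if (anyDuplicated(time) || anyDuplicated(groups) || anyDuplicated(strata))
    stop("time, group and stratum labels must be unique", call. = FALSE)

  if (anyNA(counts) || anyNA(populations))
    stop("counts and populations must not contain missing values", call. = FALSE)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(populations <= 0))
    stop("populations must be strictly positive", call. = FALSE)

  check_even_spacing(time)

  dimnames(counts) <- dimnames(populations) <- list(time, groups, strata)
  structure(
    list(counts = round(counts), populations = populations,
         time = time, groups = groups, strata = strata),
    class = "case_series"
  )
}

promote_array <- function(x) {
  if (is.null(dim(x))) x <- array(x, dim = c(length(x), 1L, 1L))
  else if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  else if (length(dim(x)) != 3L)
    stop("counts/populations must have at most 3 dimensions", call. = FALSE)
  x
}

# Periods must form a regular grid. Integer labels are read as calendar
# years and must advance by exactly 1 (a skipped year is a gap, not a
# coarser reporting interval); other numeric labels need a constant
# step; opaque labels are accepted with a warning.
check_even_spacing <- function(time) {
  num <- suppressWarnings(as.numeric(time))
  if (anyNA(num)) {
    warning("time labels are not numeric; even spacing assumed, not checked",
            call. = FALSE)
    return(invisible(TRUE))
  }
  if (length(num) > 1L) {
    d <- diff(num)
    if (any(d <= 0))
      stop("time periods must be strictly increasing", call. = FALSE)
    integerish <- all(abs(num - round(num)) < 1e-8)
    bad <- if (integerish) d != 1 else abs(d - d[1]) > 1e-8
    if (any(bad))
      stop("time periods must be evenly spaced with no gaps; offending steps after: ",
           paste(time[which(bad)], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.case_series <- function(x, ...) {
  cat("<case_series> ", length(x$time), " periods (", x$time[1], "-",
      x$time[length(x$time)], "), ", length(x$groups), " group(s), ",
      length(x$strata), " stratum/strata\n", sep = "")
  cat("  groups: ", paste(x$groups, collapse = ", "), "\n", sep = "")
  cat("  strata: ", paste(x$strata, collapse = ", "), "\n", sep = "")
  cat("  total cases: ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' @export
dim.case_series <- function(x) dim(x$counts)

#' Convert a case series to a long data frame
#'
#' @param x A [case_series()].
#' @param ... Unused.
#' @return A data frame with columns `time`, `group`, `stratum`,
#'   `count`, `population`.
#' @export
as.data.frame.case_series <- function(x, ...) {
  g <- expand.grid(time = x$time, group = x$groups, stratum = x$strata,
                   stringsAsFactors = FALSE)
  g$count <- as.vector(x$counts)
  g$population <- as.vector(x$populations)
  g
}
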