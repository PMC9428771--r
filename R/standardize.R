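#' Standard-population weights for direct age standardization
#'
#' @param stratum Character vector of age-stratum labels; must match
#'   the strata of the case series being standardized.
#' @param weight Positive weights: raw standard-population counts or
#'   normalized shares (normalization is applied internally).
#' @return An object of class `standard_population`.
#' @export
standard_population <- function(stratum, weight) {
  stratum <- as.character(stratum)
  if (length(stratum) != length(weight) || !length(stratum))
    stop("`stratum` and `weight` must be non-empty and equal length",
         call. = FALSE)
  if (anyDuplicated(stratum)) stop("duplicate stratum labels", call. = FALSE)
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  structure(list(stratum = stratum, weight = as.numeric(weight)),
            class = "standard_population")
}

#' @export
print.standard_population <- function(x, ...) {
  cat("<standard_population>", length(x$stratum), "strata\n")
  print(data.frame(stratum = x$stratum,
                   share = round(x$weight / sum(x$weight), 4)))
  invisible(x)
}

#' Read a standard-population table from CSV
#'
#' Expects columns `stratum` and `weight`.
#'
#' @param path CSV path.
#' @return A [standard_population()].
#' @export
read_standard_population <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("stratum", "weight") %in% names(df)))
    stop("standard-population CSV needs columns `stratum` and `weight`",
         call. = FALSE)
  standard_population(df$stratum, df$weight)
}

#' 2000 US standard million weights, ages 50-79
#'
#' The 5-year-band weights of the 2000 US standard million population
#' restricted to ages 50-79, as shipped with the package
#' (`inst/extdata/std_pop_2000_us_50_79.csv`). Weights are raw
#' standard-million counts; [direct_standardize()] normalizes them.
#'
#' @return A [standard_population()] with strata `"50-54"` ... `"75-79"`.
#' @export
us_standard_2000 <- function() {
  read_standard_population(
    system.file("extdata", "std_pop_2000_us_50_79.csv",
                package = "ratetrends", mustWork = TRUE))
}

#' Directly age-standardized rate draws
#'
#' For every posterior draw and period, the standardized rate is the
#' weighted average of the age-specific rate draws,
#' `SR_t = sum_i w_i * R_{it}` with the weights normalized to sum to
#' one. Strata are matched by label; any mismatch between the
#' standard population and the fitted strata is an error (silent
#' partial standardization would bias the result).
#'
#' @param fit An [fit_rw()] result with age-stratified series.
#' @param std A [standard_population()].
#' @param group Group label (default first group).
#' @param per Reporting scale (e.g. `1e5`).
#' @return A [rate_draws()] matrix of standardized rates.
#' @export
direct_standardize <- function(fit, std, group = NULL, per = 1) {
  stopifnot(inherits(fit, "rw_fit"), inherits(std, "standard_population"))
  strata <- fit$series$strata
  missing_in_data <- setdiff(std$stratum, strata)
  missing_in_std <- setdiff(strata, std$stratum)
  if (length(missing_in_data) || length(missing_in_std))
    stop("stratum labels do not match; absent from data: {",
         paste(missing_in_data, collapse = ", "), "}; absent from standard: {",
         paste(missing_in_std, collapse = ", "), "}", call. = FALSE)
  w <- std$weight[match(strata, std$stratum)]
  w <- w / sum(w)
  group <- group %||% fit$series$groups[1]
  sr <- NULL
  for (i in seq_along(strata)) {
    r <- rate_draws(fit, group = group, stratum = strata[i], per = per)
    sr <- if (is.null(sr)) w[i] * r else sr + w[i] * unclass(r)
  }
  new_rate_draws(as.matrix(unclass(sr)), fit$series$time, per,
                 label = paste0(group, "/age-standardized"))
}
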