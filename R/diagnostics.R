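#' Split R-hat convergence diagnostic
#'
#' Classic potential-scale-reduction statistic computed after
#' splitting each chain in half, so within-chain trends register as
#' between-chain disagreement. For `M` chains of length `N` it forms
#' `2M` half-chains and returns
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-half-chain
#' variance and `B` the between-half-chain variance of the means.
#' Values near 1 indicate the chains have mixed; the fit gate used by
#' [fit_rw()] is `< 1.01`.
#'
#' @param draws Numeric matrix of posterior draws with one column per
#'   chain (draws x chains).
#' @return Scalar split R-hat.
#' @export
split_rhat <- function(draws) {
  h <- split_chains(draws)
  nh <- nrow(h)
  W <- mean(apply(h, 2L, var))
  if (!is.finite(W) || W == 0)
    stop("degenerate draws: zero within-chain variance", call. = FALSE)
  B <- nh * var(colMeans(h))
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

# draws x chains -> half-chains as columns (odd trailing draw dropped)
split_chains <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L)
    stop("at least 2 chains are required", call. = FALSE)
  if (nrow(draws) < 4L)
    stop("at least 4 draws per chain are required", call. = FALSE)
  n2 <- nrow(draws) %/% 2L
  first <- draws[seq_len(n2), , drop = FALSE]
  second <- draws[n2 + seq_len(n2), , drop = FALSE]
  cbind(first, second)
}

#' Bulk effective sample size
#'
#' Multi-chain effective sample size from the combined autocorrelation
#' estimate \eqn{\hat\rho_t = 1 - (W - \overline{acov_t}) /
#' \widehat{var}^+} over split half-chains, truncated by Geyer's
#' initial monotone positive sequence.
#'
#' @inheritParams split_rhat
#' @return Scalar effective sample size, capped at the total number of
#'   draws.
#' @export
ess_bulk <- function(draws) {
  h <- split_chains(draws)
  nh <- nrow(h); M <- ncol(h)
  W <- mean(apply(h, 2L, var))
  if (!is.finite(W) || W == 0)
    stop("degenerate draws: zero within-chain variance", call. = FALSE)
  B <- nh * var(colMeans(h))
  varplus <- (nh - 1) / nh * W + B / nh

  max_lag <- nh - 1L
  acov <- sapply(seq_len(M), function(j) {
    a <- acf(h[, j], lag.max = max_lag, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
    a
  })
  # acov rows are lags 0..max_lag
  rho <- 1 - (W - rowMeans(acov)) / varplus
  rho[1L] <- 1

  # Geyer initial monotone positive sequence over lag pairs
  npairs <- (length(rho) - 1L) %/% 2L
  psum <- 0; prev <- Inf
  if (npairs > 0) {
    for (i in seq_len(npairs)) {
      pair <- rho[2L * i] + rho[2L * i + 1L]
      if (!is.finite(pair) || pair < 0) break
      pair <- min(pair, prev)  # enforce monotonicity
      psum <- psum + pair
      prev <- pair
    }
  }
  total <- nh * M
  ess <- total / (1 + 2 * psum)
  min(ess, total)
}

#' Monte Carlo standard error of the posterior mean
#'
#' `sd(draws) / sqrt(ess_bulk(draws))`: the sampling noise left in the
#' reported posterior mean. The fit gate used by [fit_rw()] requires
#' it to be below 10% of the posterior standard deviation.
#'
#' @inheritParams split_rhat
#' @return Scalar standard error.
#' @export
mcse_mean <- function(draws) {
  sd(as.vector(as.matrix(draws))) / sqrt(ess_bulk(draws))
}

#' Summarize posterior draws as mean and equal-tailed interval
#'
#' Applies a (monotone) transform per draw, then reports the posterior
#' mean and equal-tailed credible interval (2.5th/97.5th percentiles
#' at the default level). Interval endpoints are order statistics
#' (quantile type 1), so for any increasing transform `f` the interval
#' of `f(draws)` is exactly `f` of the interval of the draws.
#'
#' @param draws Numeric vector, or draws-by-periods matrix such as a
#'   [rate_draws()] object (one summary row per column).
#' @param transform Function applied to the draws before summarizing
#'   (default identity).
#' @param level Credible level (default 0.95).
#' @param quantity,group,stratum Labels stored in the output.
#' @return A `rate_summary` data frame with columns `time`, `group`,
#'   `stratum`, `quantity`, `mean`, `lwr_2.5`, `upr_97.5` (interval
#'   column names follow the level).
#' @export
summarize_draws <- function(draws, transform = identity, level = 0.95,
                            quantity = "rate", group = "all",
                            stratum = "all") {
  if (!length(draws)) stop("empty draws", call. = FALSE)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L)
  if (!all(is.finite(draws))) stop("draws must be finite", call. = FALSE)
  time <- attr(draws, "time") %||% colnames(draws) %||%
    as.character(seq_len(ncol(draws)))
  tm <- apply(draws, 2L, function(col) {
    x <- transform(col)
    c(mean(x), quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 1))
  })
  out <- data.frame(time = time, group = group, stratum = stratum,
                    quantity = quantity, mean = tm[1L, ],
                    lwr = tm[2L, ], upr = tm[3L, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[6:7] <- c(paste0("lwr_", format(100 * (1 - level) / 2)),
                       paste0("upr_", format(100 * (1 + level) / 2)))
  class(out) <- c("rate_summary", "data.frame")
  out
}

#' Convergence diagnostics for a fitted model
#'
#' Computes split R-hat, bulk ESS and Monte Carlo standard error for
#' every scalar parameter of an [fit_rw()] result (each `eta[t]`,
#' `tau`, and off-diagonal correlation when joint). Parameters failing
#' the gates (split R-hat < 1.01; MCSE below 10% of the posterior sd)
#' are listed in the `flags` attribute.
#'
#' @param fit An [fit_rw()] result.
#' @return A `diagnostics_report` data frame with columns `parameter`,
#'   `split_rhat`, `ess_bulk`, `mcse_mean`, `sd`, `ok`.
#' @export
diagnose <- function(fit) {
  stopifnot(inherits(fit, "rw_fit"))
  d <- dim(fit$eta)  # chains, draws, n, k, m
  params <- list()
  for (s in seq_len(d[5])) for (g in seq_len(d[4])) {
    for (t in seq_len(d[3]))
      params[[sprintf("eta[%s,%s,%s]", fit$series$time[t],
                      fit$series$groups[g], fit$series$strata[s])]] <-
        t(fit$eta[, , t, g, s])
    params[[sprintf("tau[%s,%s]", fit$series$groups[g],
                    fit$series$strata[s])]] <- t(fit$tau[, , g, s])
  }
  if (!is.null(fit$corr)) {
    k <- d[4]
    for (s in seq_len(d[5]))
      for (i in seq_len(k)) for (j in seq_len(k)) if (i > j)
        params[[sprintf("corr[%s,%s,%s]", fit$series$groups[i],
                        fit$series$groups[j], fit$series$strata[s])]] <-
          t(fit$corr[, , i, j, s])
  }
  rows <- lapply(names(params), function(nm) {
    x <- params[[nm]]
    sdx <- sd(as.vector(x))
    if (sdx < 1e-12) {  # constant parameter (e.g. tau at n = 1 prior-only edge)
      return(data.frame(parameter = nm, split_rhat = 1, ess_bulk = NA_real_,
                        mcse_mean = 0, sd = sdx, ok = TRUE,
                        stringsAsFactors = FALSE))
    }
    rh <- split_rhat(x); es <- ess_bulk(x); mc <- sdx / sqrt(es)
    data.frame(parameter = nm, split_rhat = rh, ess_bulk = es,
               mcse_mean = mc, sd = sdx,
               ok = rh < 1.01 && mc < 0.1 * sdx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diagnostics_report", "data.frame")
  attr(out, "flags") <- out$parameter[!out$ok]
  out
}
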