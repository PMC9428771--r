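#' Model and sampler settings for the random-walk incidence model
#'
#' The model places a first-difference (random-walk) prior on the
#' latent log risk (Poisson family) or logit risk (binomial family):
#' \deqn{\eta_t \sim N(\eta_{t-1}, \tau^2), \quad t > 1,}
#' with a diffuse Gaussian prior on \eqn{\eta_1} and a half-normal
#' prior on the walk scale \eqn{\tau}. Counts are modeled as
#' \eqn{y_t \sim Pois(P_t e^{\eta_t})} or
#' \eqn{y_t \sim Binom(P_t, logit^{-1}(\eta_t))}. With `joint = TRUE`
#' the increments of the `k` group series are multivariate normal with
#' covariance `diag(tau) %*% C %*% diag(tau)` and an LKJ prior on the
#' correlation matrix `C`.
#'
#' @param family `"poisson"` (log link; rare events) or `"binomial"`
#'   (logit link).
#' @param eta1_prior_mean,eta1_prior_sd Gaussian prior on the
#'   first-period log/logit risk. The default N(-5, 5^2) centers on a
#'   rate of `exp(-5)` (about 674 per 100,000) and is diffuse for rare
#'   diseases.
#' @param tau_prior_sd Scale of the half-normal prior on `tau`
#'   (default 1, diffuse for log-rate increments).
#' @param joint Model the group series with correlated increments.
#' @param lkj_shape Shape of the LKJ prior on the increment
#'   correlation matrix (default 2, mildly favoring independence).
#' @param chains,draws_per_chain,warmup MCMC protocol: `chains`
#'   independent chains of `draws_per_chain` iterations each, the first
#'   `warmup` discarded (defaults 4, 6000, 3000).
#' @param target_accept Step-size adaptation target in (0, 1), default
#'   0.9. [fit_rw()] automatically refits a series once at 0.99 if more
#'   than 5% of its post-warmup trajectories diverge.
#' @param seed Integer seed, expanded deterministically to per-chain
#'   (and per-series) streams.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("poisson", "binomial"),
                       eta1_prior_mean = -5, eta1_prior_sd = 5,
                       tau_prior_sd = 1,
                       joint = FALSE, lkj_shape = 2,
                       chains = 4L, draws_per_chain = 6000L, warmup = 3000L,
                       target_accept = 0.9, seed = 1L) {
  family <- match.arg(family)
  chains <- as.integer(chains)
  draws_per_chain <- as.integer(draws_per_chain)
  warmup <- as.integer(warmup)
  if (eta1_prior_sd <= 0 || tau_prior_sd <= 0 || lkj_shape <= 0)
    stop("eta1_prior_sd, tau_prior_sd and lkj_shape must be positive",
         call. = FALSE)
  if (chains < 1L || draws_per_chain < 1L || warmup < 0L)
    stop("chains and draws_per_chain must be positive, warmup nonnegative",
         call. = FALSE)
  if (warmup >= draws_per_chain)
    stop("warmup must be smaller than draws_per_chain", call. = FALSE)
  if (target_accept <= 0 || target_accept >= 1)
    stop("target_accept must lie in (0, 1)", call. = FALSE)
  structure(
    list(family = family, eta1_prior_mean = eta1_prior_mean,
         eta1_prior_sd = eta1_prior_sd, tau_prior_sd = tau_prior_sd,
         joint = isTRUE(joint), lkj_shape = lkj_shape, chains = chains,
         draws_per_chain = draws_per_chain, warmup = warmup,
         target_accept = target_accept, seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> family =", x$family,
      if (x$joint) "(joint correlated groups)" else "(independent series)", "\n")
  cat("  eta1 ~ N(", x$eta1_prior_mean, ", ", x$eta1_prior_sd, "^2); tau ~ halfN(0, ",
      x$tau_prior_sd, "^2)\n", sep = "")
  cat("  MCMC:", x$chains, "chains x", x$draws_per_chain, "draws (warmup",
      x$warmup, "), seed", x$seed, "\n")
  invisible(x)
}

#' Log prior density of one latent path
#'
#' Evaluates the joint log prior of a single latent path
#' \eqn{\eta_1,\dots,\eta_n} and walk scale \eqn{\tau}:
#' \eqn{\log N(\eta_1 \mid m_0, s_0^2) + \sum_{t\ge 2}
#' \log N(\eta_t \mid \eta_{t-1}, \tau^2)} plus the half-normal log
#' density of \eqn{\tau}.
#'
#' @param eta_path Numeric vector, the latent log/logit risks.
#' @param tau Positive scalar, the random-walk scale.
#' @param spec A [model_spec()].
#' @return Scalar log density.
#' @export
log_prior_density <- function(eta_path, tau, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("`tau` must be a positive scalar", call. = FALSE)
  n <- length(eta_path)
  if (n < 1L) stop("`eta_path` must have length >= 1", call. = FALSE)
  lp <- dnorm(eta_path[1], spec$eta1_prior_mean, spec$eta1_prior_sd, log = TRUE)
  if (n > 1L)
    lp <- lp + sum(dnorm(eta_path[-1], eta_path[-n], tau, log = TRUE))
  # half-normal: twice the normal density on the positive half-line
  lp + log(2) + dnorm(tau, 0, spec$tau_prior_sd, log = TRUE)
}

#' Log likelihood of one observed series
#'
#' Sum over periods of the Poisson log pmf at mean
#' \eqn{P_t e^{\eta_t}}, or the binomial log pmf with success
#' probability \eqn{logit^{-1}(\eta_t)} and size \eqn{P_t}.
#'
#' @param y Nonnegative integer counts.
#' @param population Populations at risk (integral for binomial).
#' @param eta_path Latent log/logit risks, same length.
#' @param family `"poisson"` or `"binomial"`.
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(y, population, eta_path,
                           family = c("poisson", "binomial")) {
  family <- match.arg(family)
  if (length(y) != length(population) || length(y) != length(eta_path))
    stop("`y`, `population` and `eta_path` must have equal length",
         call. = FALSE)
  if (family == "poisson") {
    sum(dpois(y, population * exp(eta_path), log = TRUE))
  } else {
    if (any(abs(population - round(population)) > 1e-8))
      stop("binomial family requires integral populations", call. = FALSE)
    if (any(y > population))
      stop("binomial family requires y <= population", call. = FALSE)
    sum(dbinom(y, round(population), plogis_(eta_path), log = TRUE))
  }
}

plogis_ <- function(x) 1 / (1 + exp(-x))

#' Fit the random-walk incidence model by MCMC
#'
#' Draws posterior samples of the latent risk paths `eta`, walk scales
#' `tau`, and (for `joint = TRUE`) the group correlation matrix, for
#' every (group, stratum) series of a [case_series()]. With
#' `joint = FALSE` each series is fit independently; with
#' `joint = TRUE` the groups within each stratum share correlated
#' increments (each stratum has its own scales and correlation
#' matrix). Sampling uses an adaptive Hamiltonian Monte Carlo kernel
#' on a non-centered parameterization, with a Metropolis update for
#' the correlation matrix in joint mode.
#'
#' After sampling, split R-hat, bulk effective sample size and Monte
#' Carlo standard errors are computed for every parameter
#' ([diagnose()]); if any diagnostic gate fails, a warning of class
#' `ratetrends_convergence_warning` carrying the diagnostics table is
#' raised. A post-warmup divergence rate above 5% in any chain is a
#' convergence error.
#'
#' @param series A [case_series()].
#' @param spec A [model_spec()].
#' @return An object of class `rw_fit`: list with `eta` (array
#'   `chains x draws x n x k x m`, log/logit scale), `tau`
#'   (`chains x draws x k x m`), `corr` (`chains x draws x k x k x m`
#'   or `NULL`), `series`, `spec`, `diagnostics`, `sampler_info`.
#' @export
fit_rw <- function(series, spec = model_spec()) {
  stopifnot(inherits(series, "case_series"), inherits(spec, "model_spec"))
  n <- length(series$time); k <- length(series$groups)
  m <- length(series$strata)
  if (spec$joint && k < 2L)
    stop("joint = TRUE requires at least 2 groups", call. = FALSE)
  if (spec$family == "binomial") {
    if (any(abs(series$populations - round(series$populations)) > 1e-8))
      stop("binomial family requires integral populations", call. = FALSE)
    if (any(series$counts > series$populations))
      stop("binomial family requires counts <= populations", call. = FALSE)
  }
  retained <- spec$draws_per_chain - spec$warmup
  chains <- spec$chains

  eta <- array(NA_real_, c(chains, retained, n, k, m),
               dimnames = list(NULL, NULL, series$time, series$groups,
                               series$strata))
  tau <- array(NA_real_, c(chains, retained, k, m),
               dimnames = list(NULL, NULL, series$groups, series$strata))
  corr <- if (spec$joint)
    array(NA_real_, c(chains, retained, k, k, m),
          dimnames = list(NULL, NULL, series$groups, series$groups,
                          series$strata)) else NULL
  divergent <- integer(0); accept <- numeric(0); stepsize <- numeric(0)

  series_id <- 0L
  run_one <- function(y, P, joint) {
    series_id <<- series_id + 1L
    res <- rw_sampler_cpp(y, P, spec$family, spec$eta1_prior_mean,
                          spec$eta1_prior_sd, spec$tau_prior_sd, joint,
                          spec$lkj_shape, chains, spec$draws_per_chain,
                          spec$warmup, spec$target_accept, spec$seed,
                          series_id)
    # a rare adaptation failure shows up as wholesale divergence; refit
    # once with a near-1 acceptance target (smaller step size), the
    # standard remedy for divergent Hamiltonian trajectories
    if (max(res$divergent) / retained > 0.05 && spec$target_accept < 0.99)
      res <- rw_sampler_cpp(y, P, spec$family, spec$eta1_prior_mean,
                            spec$eta1_prior_sd, spec$tau_prior_sd, joint,
                            spec$lkj_shape, chains, spec$draws_per_chain,
                            spec$warmup, 0.99, spec$seed, series_id)
    res
  }

  for (s in seq_len(m)) {
    if (spec$joint) {
      res <- run_one(matrix(series$counts[, , s], n, k),
                     matrix(series$populations[, , s], n, k), TRUE)
      # res$eta: (retained, n*k, chains)
      for (ch in seq_len(chains)) {
        eta[ch, , , , s] <- array(res$eta[, , ch], c(retained, n, k))
        tau[ch, , , s] <- res$tau[, , ch]
        corr[ch, , , , s] <- array(res$corr[, , ch], c(retained, k, k))
      }
      divergent <- c(divergent, res$divergent)
      accept <- c(accept, res$accept); stepsize <- c(stepsize, res$stepsize)
    } else {
      for (g in seq_len(k)) {
        res <- run_one(matrix(series$counts[, g, s], n, 1L),
                       matrix(series$populations[, g, s], n, 1L), FALSE)
        for (ch in seq_len(chains)) {
          eta[ch, , , g, s] <- res$eta[, , ch]
          tau[ch, , g, s] <- res$tau[, 1L, ch]
        }
        divergent <- c(divergent, res$divergent)
        accept <- c(accept, res$accept); stepsize <- c(stepsize, res$stepsize)
      }
    }
  }

  fit <- structure(
    list(eta = eta, tau = tau, corr = corr, series = series, spec = spec,
         diagnostics = NULL,
         sampler_info = list(divergent = divergent, accept = accept,
                             stepsize = stepsize, retained = retained)),
    class = "rw_fit"
  )

  div_rate <- max(divergent) / retained
  if (div_rate > 0.05) {
    diag_tab <- diagnose(fit)
    cond <- structure(
      class = c("ratetrends_convergence_error", "error", "condition"),
      list(message = sprintf(
        "divergence rate %.1f%% exceeds 5%%; posterior geometry not explored reliably",
        100 * div_rate), call = sys.call(-1), diagnostics = diag_tab))
    stop(cond)
  }

  fit$diagnostics <- diagnose(fit)
  flags <- attr(fit$diagnostics, "flags")
  if (length(flags)) {
    cond <- structure(
      class = c("ratetrends_convergence_warning", "warning", "condition"),
      list(message = paste0(
        "convergence gates failed for ", length(flags), " parameter(s): ",
        paste(utils::head(flags, 5L), collapse = ", "),
        if (length(flags) > 5L) ", ..."),
        call = sys.call(-1), diagnostics = fit$diagnostics))
    warning(cond)
  }
  fit
}

#' @export
print.rw_fit <- function(x, ...) {
  d <- dim(x$eta)
  cat("<rw_fit> ", x$spec$family, " random-walk model",
      if (x$spec$joint) " (joint)", "\n", sep = "")
  cat("  ", d[3], " periods x ", d[4], " group(s) x ", d[5],
      " stratum/strata\n", sep = "")
  cat("  ", d[1], " chains x ", d[2], " retained draws\n", sep = "")
  dg <- x$diagnostics
  if (!is.null(dg))
    cat("  max split R-hat ", round(max(dg$split_rhat), 4),
        "; min bulk ESS ", round(min(dg$ess_bulk)), "\n", sep = "")
  invisible(x)
}

#' Extract rate-scale posterior draws
#'
#' Returns the posterior draws of the incidence rate (Poisson:
#' `exp(eta)`; binomial: `plogis(eta)`) for one (group, stratum)
#' series, pooled across chains, as a draws-by-period matrix. This is
#' the common currency consumed by the derived-quantity functions
#' ([cumulative_percent_change()], [aapc()], [theil_index()], ...);
#' [direct_standardize()] produces the same shape for age-standardized
#' rates.
#'
#' @param fit An [fit_rw()] result.
#' @param group,stratum Labels (default: first group / first stratum).
#' @param per Reporting scale, e.g. `1e5` for rates per 100,000
#'   (default 1: raw risk per person).
#' @return A numeric matrix (total draws x periods) of class
#'   `rate_draws`, with `time`, `per` and `label` attributes.
#' @export
rate_draws <- function(fit, group = NULL, stratum = NULL, per = 1) {
  stopifnot(inherits(fit, "rw_fit"))
  group <- group %||% fit$series$groups[1]
  stratum <- stratum %||% fit$series$strata[1]
  gi <- match(group, fit$series$groups)
  si <- match(stratum, fit$series$strata)
  if (is.na(gi)) stop("unknown group: ", group, call. = FALSE)
  if (is.na(si)) stop("unknown stratum: ", stratum, call. = FALSE)
  d <- dim(fit$eta)
  e <- matrix(fit$eta[, , , gi, si], d[1] * d[2], d[3])
  r <- if (fit$spec$family == "poisson") exp(e) else plogis_(e)
  new_rate_draws(r * per, fit$series$time, per,
                 label = paste0(group, "/", stratum))
}

new_rate_draws <- function(mat, time, per, label = "") {
  colnames(mat) <- time
  structure(mat, class = c("rate_draws", "matrix", "array"),
            time = time, per = per, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
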