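#' Simulate model-consistent surveillance data
#'
#' Runs the generative model forward: latent log (or logit) risks
#' follow a Gaussian random walk `eta_t = eta_{t-1} + increment` with
#' scale `tau` (multivariate-normal increments across groups when a
#' correlation matrix is supplied), and counts are drawn
#' `Poisson(P_t * exp(eta_t))` or `Binomial(P_t, plogis(eta_t))`.
#' Populations may grow at a fixed per-period rate, which makes excess
#' cases grow under a persistent rate gap — the dynamic that motivates
#' reporting EC alongside RD.
#'
#' Each simulated series draws from its own RNG stream derived
#' deterministically from `seed`, so output is reproducible and
#' per-series draws do not interleave.
#'
#' @param n_periods Number of evenly spaced periods.
#' @param groups,strata Character vectors of labels (defaults a single
#'   `"all"` group/stratum).
#' @param eta1 First-period log/logit risk; scalar or `k x m` matrix.
#' @param tau Random-walk scale(s) >= 0; scalar or `k x m` matrix.
#' @param populations Populations at risk: scalar, length-`n` vector,
#'   or `n x k x m` array (binomial requires integers).
#' @param family `"poisson"` or `"binomial"`.
#' @param corr Optional `k x k` correlation matrix for across-group
#'   increments (shared by all strata).
#' @param growth Per-period multiplicative population growth rate
#'   (default 0; 0.02 means +2% per period), applied when
#'   `populations` is scalar or per-group.
#' @param time Optional period labels (default `1:n_periods` offset to
#'   look like calendar years starting at 1999).
#' @param seed Integer master seed.
#' @return A list with elements `series` (a [case_series()]) and
#'   `truth` (class `simulation_truth`: `eta` array `n x k x m`,
#'   `tau`, `corr`, `populations`, `seed`).
#' @export
simulate_caseseries <- function(n_periods = 20, groups = "all",
                                strata = "all", eta1 = -5, tau = 0.05,
                                populations = 1e5,
                                family = c("poisson", "binomial"),
                                corr = NULL, growth = 0, time = NULL,
                                seed = 1L) {
  family <- match.arg(family)
  n <- as.integer(n_periods)
  if (n < 1L) stop("n_periods must be >= 1", call. = FALSE)
  k <- length(groups); m <- length(strata)
  eta1 <- expand_km(eta1, k, m, "eta1")
  tau <- expand_km(tau, k, m, "tau")
  if (any(tau < 0)) stop("tau must be nonnegative", call. = FALSE)
  if (!is.null(corr)) {
    corr <- as.matrix(corr)
    if (!identical(dim(corr), c(k, k)) ||
        max(abs(corr - t(corr))) > 1e-10 || any(abs(diag(corr) - 1) > 1e-10))
      stop("`corr` must be a k x k correlation matrix", call. = FALSE)
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("`corr` must be a valid correlation matrix (positive semi-definite)",
           call. = FALSE)
  }

  P <- build_populations(populations, n, k, m, growth)
  if (family == "binomial" && any(abs(P - round(P)) > 1e-8))
    stop("binomial family requires integral populations", call. = FALSE)
  time <- time %||% as.character(1998L + seq_len(n))

  # deterministic per-series substreams: one per stratum when increments
  # are correlated across groups, one per (group, stratum) otherwise
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  substreams <- sample.int(.Machine$integer.max %/% 2L, k * m + m)

  eta <- array(NA_real_, c(n, k, m))
  if (!is.null(corr)) {
    L <- t(chol(corr + diag(1e-12, k)))
    for (s in seq_len(m)) {
      set.seed(substreams[k * m + s])
      z1 <- rnorm(k)
      eta[1, , s] <- eta1[, s]
      if (n > 1L) for (t in 2:n) {
        inc <- as.vector(L %*% rnorm(k)) * tau[, s]
        eta[t, , s] <- eta[t - 1, , s] + inc
      }
    }
  } else {
    for (s in seq_len(m)) for (g in seq_len(k)) {
      set.seed(substreams[(s - 1L) * k + g])
      path <- numeric(n)
      path[1] <- eta1[g, s]
      if (n > 1L)
        path[2:n] <- eta1[g, s] + cumsum(rnorm(n - 1L, 0, tau[g, s]))
      eta[, g, s] <- path
    }
  }

  counts <- array(NA_real_, c(n, k, m))
  for (s in seq_len(m)) for (g in seq_len(k)) {
    set.seed(substreams[(s - 1L) * k + g] + 1L)
    counts[, g, s] <- if (family == "poisson")
      rpois(n, P[, g, s] * exp(eta[, g, s]))
    else rbinom(n, round(P[, g, s]), plogis_(eta[, g, s]))
  }

  series <- case_series(counts, P, time = time, groups = groups,
                        strata = strata)
  truth <- structure(
    list(eta = array(eta, c(n, k, m),
                     dimnames = list(time, groups, strata)),
         tau = tau, corr = corr, populations = P, seed = as.integer(seed)),
    class = "simulation_truth")
  list(series = series, truth = truth)
}

expand_km <- function(x, k, m, what) {
  if (length(x) == 1L) return(matrix(x, k, m))
  x <- as.matrix(x)
  if (nrow(x) == k && ncol(x) == m) return(x)
  if (length(x) == k && m == 1L) return(matrix(x, k, 1L))
  stop("`", what, "` must be scalar or k x m", call. = FALSE)
}

build_populations <- function(populations, n, k, m, growth) {
  if (is.array(populations) && length(dim(populations)) == 3L) {
    if (!identical(dim(populations), c(n, k, m)))
      stop("populations array must be n x k x m", call. = FALSE)
    P <- populations
  } else if (length(populations) == 1L) {
    P <- array(populations * (1 + growth)^(seq_len(n) - 1L), c(n, k, m))
  } else if (length(populations) == n) {
    P <- array(populations, c(n, k, m))
  } else if (length(populations) == k) {
    base <- outer(seq_len(n) - 1L, seq_len(k),
                  function(t, g) populations[g] * (1 + growth)^t)
    P <- array(base, c(n, k, m))
  } else {
    stop("populations must be scalar, length n, length k, or n x k x m array",
         call. = FALSE)
  }
  if (any(P <= 0)) stop("populations must be positive", call. = FALSE)
  P
}
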