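# Shared fixtures. Everything is generated in code at test time; the
# stochastic reference fit is built once per test run and reused.

.fixture_cache <- new.env(parent = emptyenv())

# A degenerate "fit" whose rate draws are exact constants: every chain
# and draw carries eta = log(rate). Lets algebraic identities be
# checked without Monte Carlo noise.
make_fixed_fit <- function(rates, populations, time = NULL, groups = NULL,
                           strata = NULL, ndraw = 20L, nchain = 2L) {
  rates <- ratetrends:::promote_array(rates)
  populations <- if (length(populations) == 1L)
    array(populations, dim(rates))
  else ratetrends:::promote_array(populations)
  n <- dim(rates)[1]; k <- dim(rates)[2]; m <- dim(rates)[3]
  time <- time %||% as.character(seq(1999, length.out = n))
  groups <- groups %||% paste0("g", seq_len(k))
  strata <- strata %||% if (m == 1) "all" else paste0("s", seq_len(m))
  series <- case_series(round(rates * populations), populations,
                        time = time, groups = groups, strata = strata)
  eta <- array(rep(log(rates), each = nchain * ndraw),
               c(nchain, ndraw, n, k, m),
               dimnames = list(NULL, NULL, time, groups, strata))
  tau <- array(0.05, c(nchain, ndraw, k, m),
               dimnames = list(NULL, NULL, groups, strata))
  structure(list(eta = eta, tau = tau, corr = NULL, series = series,
                 spec = model_spec(chains = nchain,
                                   draws_per_chain = ndraw + 1L, warmup = 1L),
                 diagnostics = NULL,
                 sampler_info = list(divergent = 0L, accept = 1,
                                     stepsize = NA, retained = ndraw)),
            class = "rw_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One genuine MCMC fit shared across test files: 2 groups x 2 age
# strata, 10 periods, group "d" at roughly twice the risk of "a".
shared_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    sim <- simulate_caseseries(
      n_periods = 10, groups = c("d", "a"), strata = c("50-54", "55-59"),
      eta1 = matrix(c(-6.2, -6.9, -5.8, -6.5), 2, 2), tau = 0.04,
      populations = 5e5, seed = 42)
    .fixture_cache$sim <- sim
    .fixture_cache$fit <- suppressWarnings(
      fit_rw(sim$series, model_spec(chains = 2, draws_per_chain = 1500,
                                    warmup = 700, seed = 7)))
  }
  .fixture_cache$fit
}

shared_sim <- function() {
  shared_fit()
  .fixture_cache$sim
}

# A CDC-Wonder-style export with `n_rows` data rows and a notes footer.
write_wonder_fixture <- function(path, n_rows = 20, footer = TRUE) {
  years <- seq(1999, length.out = n_rows)
  lines <- c("Year\tCount\tPopulation",
             paste(years, 100 + seq_len(n_rows), 100000, sep = "\t"))
  if (footer)
    lines <- c(lines, "\"---\"", "\"Notes\"",
               "\"Queried from the incidence database.\"",
               "\"Suppressed counts are not shown.\"", "\"---\"",
               "\"Query date: 2026-01-01\"")
  writeLines(lines, path)
  path
}
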