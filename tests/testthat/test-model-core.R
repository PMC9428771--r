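test_that("log prior density matches the closed-form Gaussian pieces", {
  spec <- model_spec()
  # n = 1 at the prior mode: N(-5, 25) at -5 plus the half-normal term
  tau <- 0.3
  gauss_at_mode <- -0.5 * log(2 * pi * 25)
  half_norm <- log(2) - 0.5 * log(2 * pi) - 0.5 * tau^2
  expect_equal(log_prior_density(-5, tau, spec), gauss_at_mode + half_norm,
               tolerance = 1e-12)

  # constant path: each increment term is the N(0, tau^2) mode density
  lp3 <- log_prior_density(c(-5, -5, -5), tau, spec)
  expect_equal(lp3 - log_prior_density(-5, tau, spec),
               2 * (-0.5 * log(2 * pi * tau^2)), tolerance = 1e-12)

  # doubling tau_prior_sd changes only the half-normal term
  spec2 <- model_spec(tau_prior_sd = 2)
  delta <- log_prior_density(c(-5.1, -5, -4.8), tau, spec2) -
    log_prior_density(c(-5.1, -5, -4.8), tau, spec)
  expect_equal(delta,
               (log(2) + dnorm(tau, 0, 2, log = TRUE)) -
                 (log(2) + dnorm(tau, 0, 1, log = TRUE)), tolerance = 1e-12)

  expect_error(log_prior_density(-5, -1, spec), "positive")
})

test_that("log likelihood matches hand-computed pmf values", {
  # Poisson at y = 0: log pmf is -mu = -1000 * exp(-5)
  expect_equal(log_likelihood(0, 1000, -5, "poisson"), -1000 * exp(-5),
               tolerance = 1e-12)
  # binomial at eta = 0 has success probability exactly 1/2
  expect_equal(log_likelihood(3, 10, 0, "binomial"),
               dbinom(3, 10, 0.5, log = TRUE), tolerance = 1e-12)
  expect_error(log_likelihood(11, 10, 0, "binomial"), "y <= population")

  # the per-period Poisson term is maximized at the integer part of the
  # mean (brute-force scan over y)
  for (mu in c(2.3, 3.7, 7.1)) {
    eta <- log(mu / 50)
    ll <- vapply(0:50, function(y) log_likelihood(y, 50, eta, "poisson"), 0)
    expect_equal(which.max(ll) - 1L, floor(mu))
  }
})

test_that("fit recovers a constant risk within posterior uncertainty", {
  sim <- simulate_caseseries(n_periods = 20, eta1 = log(100 / 1e5), tau = 0,
                             populations = 1e6, seed = 21)
  fit <- suppressWarnings(
    fit_rw(sim$series, model_spec(chains = 2, draws_per_chain = 1500,
                                  warmup = 700, seed = 3)))
  rd <- rate_draws(fit, per = 1e5)
  post_mean <- colMeans(rd)
  post_sd <- apply(rd, 2, sd)
  expect_true(all(abs(post_mean - 100) <= 3 * post_sd))
  # per-period MLE stays close to the smoothed posterior path
  mle <- sim$series$counts[, 1, 1] / sim$series$populations[, 1, 1] * 1e5
  expect_lt(mean(abs(post_mean - mle)), 3)
})

test_that("a single-period fit with large counts concentrates at y/P", {
  s1 <- case_series(10000, 1e7, time = "1999")
  fit <- suppressWarnings(
    fit_rw(s1, model_spec(chains = 2, draws_per_chain = 2000, warmup = 900,
                          seed = 5)))
  r <- summarize_draws(rate_draws(fit, per = 1e5))
  expect_equal(r$mean, 100, tolerance = 0.02)
})

test_that("the posterior matches an independent Gibbs sampler (JAGS)", {
  library(rjags)
  sim <- simulate_caseseries(n_periods = 10, eta1 = -6, tau = 0.08,
                             populations = 2e5, seed = 7)
  y <- sim$series$counts[, 1, 1]; P <- sim$series$populations[, 1, 1]
  model <- "model {
    eta[1] ~ dnorm(-5, 1/25)
    for (t in 2:n) { eta[t] ~ dnorm(eta[t-1], pow(tau, -2)) }
    tau ~ dnorm(0, 1) T(0,)
    for (t in 1:n) { y[t] ~ dpois(P[t] * exp(eta[t])) }
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = y, P = P, n = length(y)),
                          n.chains = 2, n.adapt = 1000, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  samp <- as.matrix(rjags::coda.samples(jm, c("eta", "tau"), 12000, thin = 3,
                                        progress.bar = "none"))
  fit <- suppressWarnings(
    fit_rw(sim$series, model_spec(chains = 4, draws_per_chain = 4000,
                                  warmup = 1500, seed = 13)))
  hmc_mean <- apply(fit$eta[, , , 1, 1], 3, mean)
  jags_mean <- colMeans(samp)[seq_along(y)]
  jags_sd <- apply(samp, 2, sd)[seq_along(y)]
  expect_true(all(abs(hmc_mean - jags_mean) < 0.2 * jags_sd))
  expect_equal(mean(fit$tau), mean(samp[, "tau"]), tolerance = 0.15)
})

test_that("identical seed, spec and data give identical draws", {
  sim <- simulate_caseseries(n_periods = 6, populations = 1e5, seed = 2)
  spec <- model_spec(chains = 2, draws_per_chain = 400, warmup = 200, seed = 99)
  f1 <- suppressWarnings(fit_rw(sim$series, spec))
  f2 <- suppressWarnings(fit_rw(sim$series, spec))
  expect_identical(f1$eta, f2$eta)
  expect_identical(f1$tau, f2$tau)
})

test_that("joint fits keep valid correlation draws and stay near zero for independent series", {
  sim <- simulate_caseseries(n_periods = 15, groups = c("a", "b"), eta1 = -6,
                             tau = 0.05, populations = 1e6, seed = 3)
  fit <- suppressWarnings(
    fit_rw(sim$series, model_spec(joint = TRUE, chains = 2,
                                  draws_per_chain = 2500, warmup = 1000,
                                  seed = 11)))
  expect_true(all(fit$tau > 0))
  co <- fit$corr
  expect_true(all(abs(co[, , 1, 1, 1] - 1) < 1e-10))
  expect_true(all(abs(co[, , 2, 2, 1] - 1) < 1e-10))
  expect_true(all(abs(co[, , 1, 2, 1] - co[, , 2, 1, 1]) < 1e-10))
  expect_true(all(abs(co[, , 1, 2, 1]) <= 1))
  # simulation truth is independence; wide band honors the LKJ prior pull
  expect_gt(mean(co[, , 1, 2, 1]), -0.5)
  expect_lt(mean(co[, , 1, 2, 1]), 0.5)
  expect_error(fit_rw(simulate_caseseries(5, seed = 1)$series,
                      model_spec(joint = TRUE)), "at least 2 groups")
})

test_that("tau draws are positive and rescaling populations only sharpens the fit", {
  fit <- shared_fit()
  expect_true(all(fit$tau > 0))

  sim_small <- simulate_caseseries(n_periods = 12, eta1 = log(100 / 1e5),
                                   tau = 0.03, populations = 1e5, seed = 17)
  sim_big <- simulate_caseseries(n_periods = 12, eta1 = log(100 / 1e5),
                                 tau = 0.03, populations = 1e6, seed = 17)
  spec <- model_spec(chains = 2, draws_per_chain = 1200, warmup = 600, seed = 8)
  f_small <- suppressWarnings(fit_rw(sim_small$series, spec))
  f_big <- suppressWarnings(fit_rw(sim_big$series, spec))
  r_small <- rate_draws(f_small, per = 1e5)
  r_big <- rate_draws(f_big, per = 1e5)
  sd_small <- apply(r_small, 2, sd); sd_big <- apply(r_big, 2, sd)
  expect_lt(median(sd_big / sd_small), 1)
  expect_true(all(abs(colMeans(r_big) - colMeans(r_small)) <=
                    3 * pmax(sd_small, sd_big)))
})

test_that("model_spec rejects invalid settings", {
  expect_error(model_spec(warmup = 6000, draws_per_chain = 6000), "warmup")
  expect_error(model_spec(eta1_prior_sd = 0), "positive")
  expect_error(model_spec(tau_prior_sd = -1), "positive")
})
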