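test_that("tau = 0 freezes the walk and Poisson count moments check out", {
  sim <- simulate_caseseries(n_periods = 10, eta1 = -5, tau = 0,
                             populations = 1e6, seed = 4)
  expect_true(all(sim$truth$eta == -5))

  long <- simulate_caseseries(n_periods = 1000, eta1 = -5, tau = 0,
                              populations = 1e6, seed = 5)
  mu <- exp(-5) * 1e6
  expect_lt(abs(mean(long$series$counts) - mu), 3 * sqrt(mu / 1000))
})

test_that("same seed reproduces output bit-exactly; different seeds differ", {
  a <- simulate_caseseries(n_periods = 8, groups = c("x", "y"), seed = 12)
  b <- simulate_caseseries(n_periods = 8, groups = c("x", "y"), seed = 12)
  expect_identical(a$series$counts, b$series$counts)
  expect_identical(a$truth$eta, b$truth$eta)
  c_ <- simulate_caseseries(n_periods = 8, groups = c("x", "y"), seed = 13)
  expect_false(identical(a$series$counts, c_$series$counts))
})

test_that("empirical increment variance tracks tau^2 over long horizons", {
  for (tau in c(0.02, 0.1)) {
    sim <- simulate_caseseries(n_periods = 5000, eta1 = -5, tau = tau,
                               populations = 1e3, seed = 31)
    incs <- diff(sim$truth$eta[, 1, 1])
    expect_equal(var(incs), tau^2, tolerance = 0.1)
  }
})

test_that("identity correlation leaves cross-group increments uncorrelated", {
  sim <- simulate_caseseries(n_periods = 500, groups = c("x", "y"),
                             eta1 = -5, tau = 0.05, populations = 1e5,
                             corr = diag(2), seed = 9)
  incs <- apply(sim$truth$eta[, , 1], 2, diff)
  expect_lt(abs(cor(incs[, 1], incs[, 2])), 0.1)

  # a strong positive correlation shows up in the increments
  rho <- matrix(c(1, 0.9, 0.9, 1), 2)
  sim2 <- simulate_caseseries(n_periods = 500, groups = c("x", "y"),
                              eta1 = -5, tau = 0.05, populations = 1e5,
                              corr = rho, seed = 9)
  incs2 <- apply(sim2$truth$eta[, , 1], 2, diff)
  expect_gt(cor(incs2[, 1], incs2[, 2]), 0.7)
})

test_that("population growth schedules and input validation behave", {
  sim <- simulate_caseseries(n_periods = 5, populations = 1e5, growth = 0.02,
                             seed = 2)
  P <- unname(sim$series$populations[, 1, 1])
  expect_equal(P, 1e5 * 1.02^(0:4), tolerance = 1e-12)

  expect_error(simulate_caseseries(n_periods = 3, tau = -0.1), "nonnegative")
  expect_error(simulate_caseseries(n_periods = 3, populations = -5), "positive")
  expect_error(simulate_caseseries(n_periods = 3, groups = c("a", "b"),
                                   corr = matrix(c(1, 2, 2, 1), 2)),
               "correlation")
  expect_error(simulate_caseseries(n_periods = 3, family = "binomial",
                                   populations = 100.5), "integral")
})

test_that("binomial simulation respects count bounds", {
  sim <- simulate_caseseries(n_periods = 10, eta1 = 0, tau = 0.1,
                             populations = 500, family = "binomial", seed = 6)
  expect_true(all(sim$series$counts <= sim$series$populations))
  # inverse-logit(0) = 0.5: counts should hover near half the population
  expect_equal(mean(sim$series$counts / 500), 0.5, tolerance = 0.1)
})
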