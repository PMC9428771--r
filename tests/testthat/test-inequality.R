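test_that("pairwise measures match hand arithmetic on point rates", {
  # d = 188, a = 144 per 100k -> RD = 44 per 100k
  fit <- make_fixed_fit(array(c(188, 144) / 1e5, c(1, 2, 1)), 1e5,
                        groups = c("d", "a"))
  pw <- pairwise_inequality(fit, "d", "a", per = 1e5)
  expect_equal(unique(as.vector(pw$rd)), 44, tolerance = 1e-10)
  expect_equal(unique(as.vector(pw$rr)), 188 / 144, tolerance = 1e-12)
  expect_equal(unique(as.vector(pw$par)), 44 / 188, tolerance = 1e-12)

  # RD of 35 per 100k over a population of 100k -> 35 excess cases
  fit2 <- make_fixed_fit(array(c(135, 100) / 1e5, c(1, 2, 1)), 1e5,
                         groups = c("d", "a"))
  pw2 <- pairwise_inequality(fit2, "d", "a", per = 1e5)
  expect_equal(unique(as.vector(pw2$ec)), 35, tolerance = 1e-10)

  # equal rates: RR 1, RD 0, EC 0
  fit3 <- make_fixed_fit(array(c(100, 100) / 1e5, c(1, 2, 1)), 1e5,
                         groups = c("d", "a"))
  pw3 <- pairwise_inequality(fit3, "d", "a", per = 1e5)
  expect_equal(unique(as.vector(pw3$rr)), 1)
  expect_equal(unique(as.vector(pw3$rd)), 0)
  expect_equal(unique(as.vector(pw3$ec)), 0)

  expect_error(pairwise_inequality(fit, "d", "d"), "must differ")
})

test_that("age-standardized inequality sums excess cases within strata", {
  # 2 strata, rates d = (100, 200), a = (80, 150) per 100k, P_d = 50k each:
  # EC = (20 + 50) * 0.5 = 35 cases; PAR = 35 / 150
  rates <- array(c(100, 80, 200, 150) / 1e5, c(1, 2, 2))
  fit <- make_fixed_fit(rates, 5e4, groups = c("d", "a"),
                        strata = c("50-54", "55-59"))
  std <- standard_population(c("50-54", "55-59"), c(0.5, 0.5))
  sp <- standardized_pairwise(fit, std, "d", "a", per = 1e5)
  expect_equal(unique(as.vector(sp$ec)), 35, tolerance = 1e-10)
  expect_equal(unique(as.vector(sp$par)), 35 / 150, tolerance = 1e-12)
  expect_equal(unique(as.vector(sp$rd)), 150 - 115, tolerance = 1e-10)

  # equal stratum rates across groups: EC = 0, SRD = 0
  fit_eq <- make_fixed_fit(array(c(1, 1, 2, 2) / 1e3, c(1, 2, 2)), 5e4,
                           groups = c("d", "a"), strata = c("50-54", "55-59"))
  sp_eq <- standardized_pairwise(fit_eq, std, "d", "a")
  expect_equal(unique(as.vector(sp_eq$ec)), 0)
  expect_equal(unique(as.vector(sp_eq$rd)), 0)

  # one stratum: standardized measures collapse to the crude ones
  fit1 <- make_fixed_fit(array(c(188, 144) / 1e5, c(1, 2, 1)), 1e5,
                         groups = c("d", "a"))
  std1 <- standard_population("all", 1)
  sp1 <- standardized_pairwise(fit1, std1, "d", "a", per = 1e5)
  pw1 <- pairwise_inequality(fit1, "d", "a", per = 1e5)
  for (q in c("rr", "rd", "par", "ec"))
    expect_equal(as.vector(sp1[[q]]), as.vector(pw1[[q]]), tolerance = 1e-12)
})

test_that("PAR and RR are exact algebraic complements per draw", {
  fit <- shared_fit()
  pw <- pairwise_inequality(fit, "d", "a", stratum = "50-54")
  expect_equal(as.vector(pw$par), as.vector(1 - 1 / pw$rr), tolerance = 1e-12)
  # cumulative PAR is a burden-weighted mean of the per-period PARs
  expect_true(all(pw$cum_par >= apply(pw$par, 1, min) - 1e-12))
  expect_true(all(pw$cum_par <= apply(pw$par, 1, max) + 1e-12))
  # cumulative EC telescopes
  expect_equal(pw$cum_ec, rowSums(pw$ec), tolerance = 1e-12)
})

test_that("par_to_rr evaluates and inverts the published conversion", {
  expect_equal(par_to_rr(0.5), 2)
  expect_equal(par_to_rr(0.25), 4 / 3, tolerance = 1e-12)
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_equal(1 - 1 / par_to_rr(grid), grid, tolerance = 1e-12)
  expect_error(par_to_rr(0), "strictly")
  expect_error(par_to_rr(1), "strictly")
  expect_error(par_to_rr(1.2), "strictly")
})

test_that("the Theil index matches hand evaluation and its known limits", {
  # equal rates: burden shares equal population shares -> T = 0
  fit_eq <- make_fixed_fit(array(c(1e-3, 1e-3), c(1, 2, 1)), 1e5,
                           groups = c("x", "y"))
  th0 <- theil_index(fit_eq)
  expect_true(all(abs(th0$total) < 1e-12))

  # equal populations, burden shares (0.75, 0.25):
  # T = 0.75 log 1.5 + 0.25 log 0.5
  fit2 <- make_fixed_fit(array(c(300, 100) / 1e5, c(1, 2, 1)), 1e5,
                         groups = c("x", "y"))
  th2 <- theil_index(fit2)
  expect_equal(unique(as.vector(th2$total)),
               0.75 * log(1.5) + 0.25 * log(0.5), tolerance = 1e-12)
  expect_equal(unique(th2$components[, 1, "x"]), 0.75 * log(1.5),
               tolerance = 1e-12)

  # all burden concentrated in one of three equal groups -> T -> log 3
  fit3 <- make_fixed_fit(array(c(100, 1e-7, 1e-7) / 1e5, c(1, 3, 1)), 1e5,
                         groups = c("x", "y", "z"))
  th3 <- theil_index(fit3)
  expect_equal(unique(as.vector(th3$total)), log(3), tolerance = 1e-4)

  expect_error(theil_index(fit_eq, groups = "x"), "at least 2")
  # T >= 0 on genuine posterior draws; invariant to population rescaling
  fit <- shared_fit()
  th <- theil_index(fit, stratum = "50-54")
  expect_true(all(th$total >= -1e-12))
  fit_resc <- fit
  fit_resc$series$populations <- fit$series$populations * 10
  expect_equal(as.vector(theil_index(fit_resc, stratum = "50-54")$total),
               as.vector(th$total), tolerance = 1e-12)
})

test_that("the Theil decomposition is additive and matches the leaf index", {
  set.seed(202)
  rates <- array(runif(4, 50, 250) / 1e5, c(1, 4, 1))
  pops <- array(runif(4, 2e4, 2e5), c(1, 4, 1))
  fit <- make_fixed_fit(rates, pops, groups = c("u1a", "u1b", "u2a", "u2b"))
  nest <- c(u1a = "u1", u1b = "u1", u2a = "u2", u2b = "u2")
  dec <- theil_decomposition(fit, nest)
  expect_equal(as.vector(dec$between + dec$within), as.vector(dec$total),
               tolerance = 1e-10)
  expect_equal(as.vector(dec$total), as.vector(theil_index(fit)$total),
               tolerance = 1e-12)

  # internally homogeneous units: within vanishes
  hom <- make_fixed_fit(array(c(2e-3, 2e-3, 5e-4, 5e-4), c(1, 4, 1)),
                        array(c(1e5, 3e5, 2e5, 1e5), c(1, 4, 1)),
                        groups = c("u1a", "u1b", "u2a", "u2b"))
  dec_hom <- theil_decomposition(hom, nest)
  expect_true(all(abs(dec_hom$within) < 1e-12))
  expect_equal(as.vector(dec_hom$between), as.vector(dec_hom$total),
               tolerance = 1e-12)

  # a single unit: between vanishes
  one <- theil_decomposition(fit, c(u1a = "u", u1b = "u", u2a = "u",
                                    u2b = "u"))
  expect_true(all(abs(one$between) < 1e-12))
  expect_equal(as.vector(one$within), as.vector(one$total), tolerance = 1e-12)

  expect_error(theil_decomposition(fit, c(u1a = "u")), "every group")

  # additivity holds per draw on genuine posteriors too
  dec_post <- theil_decomposition(shared_fit(), c(d = "metro", a = "rural"),
                                  stratum = "55-59")
  expect_equal(as.vector(dec_post$between + dec_post$within),
               as.vector(dec_post$total), tolerance = 1e-10)
})
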