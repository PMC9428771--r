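test_that("config validation fires before any compute", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Year,Count,Population", "1999,5,1000", "2000,7,1000"), f)
  expect_error(run_config(input = f, draws = 100, warmup = 100), "warmup")
  expect_error(run_config(input = f, aapc_window = 1), "aapc_window")
  expect_error(run_config(input = "no-such-file.csv"), "not found")
  expect_error(run_config(input = f, group_d = "d"), "together")
})

test_that("key = value config files parse with flag-style overrides", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Year,Count,Population", "1999,5,1000", "2000,7,1000"), f)
  cfg_file <- tempfile(fileext = ".cfg")
  writeLines(c("# surveillance run", paste0("input = ", f),
               "draws = 500", "warmup = 200", "seed = 3",
               "column.time = Year", "column.count = Count",
               "column.population = Population"), cfg_file)
  cfg <- read_run_config(cfg_file)
  expect_equal(cfg$draws, 500L)
  expect_equal(cfg$seed, 3L)
  cfg2 <- read_run_config(cfg_file, seed = 11, chains = 2)
  expect_equal(cfg2$seed, 11L)
  expect_equal(cfg2$chains, 2L)
  writeLines("draws 500", cfg_file)
  expect_error(read_run_config(cfg_file), "malformed")
})

test_that("the full workflow writes every configured output with passing gates", {
  sim <- simulate_caseseries(
    n_periods = 8, groups = c("d", "a"), strata = c("50-54", "55-59"),
    eta1 = matrix(c(-6, -6.6, -5.7, -6.3), 2, 2), tau = 0.03,
    populations = 1e6, seed = 30)
  input <- tempfile(fileext = ".txt")
  write_caseseries(sim$series, input, "wonder")
  std_file <- tempfile(fileext = ".csv")
  writeLines(c("stratum,weight", "50-54,62716", "55-59,48454"), std_file)
  out <- tempfile("rtout")
  cfg <- run_config(
    input = input, dialect = "wonder",
    chains = 2, draws = 2200, warmup = 900, seed = 14,
    std_pop = std_file, group_d = "d", group_a = "a", aapc_window = 4,
    out = out)
  res <- run_surveillance(cfg, quiet = TRUE)
  expect_equal(res$status, 0L)
  for (f in c("rates.csv", "change.csv", "diagnostics.csv",
              "standardized.csv", "inequality.csv", "manifest.txt"))
    expect_true(file.exists(file.path(out, f)), label = f)

  rates <- read.csv(file.path(out, "rates.csv"), check.names = FALSE)
  expect_setequal(unique(rates$group), c("d", "a"))
  expect_equal(nrow(rates), 8 * 2 * 2)
  ineq <- read.csv(file.path(out, "inequality.csv"), check.names = FALSE)
  expect_true(all(c("rate_ratio", "rate_difference", "attributable_risk",
                    "excess_cases", "cumulative_excess_cases",
                    "cumulative_attributable_risk") %in% ineq$quantity))
  dgn <- read.csv(file.path(out, "diagnostics.csv"))
  expect_true(all(dgn$split_rhat < 1.01))

  # rerunning with the same seed is byte-identical
  out2 <- tempfile("rtout2")
  cfg2 <- run_config(input = input, dialect = "wonder", chains = 2,
                     draws = 2200, warmup = 900, seed = 14,
                     std_pop = std_file, group_d = "d", group_a = "a",
                     aapc_window = 4, out = out2)
  run_surveillance(cfg2, quiet = TRUE)
  expect_identical(readLines(file.path(out, "rates.csv")),
                   readLines(file.path(out2, "rates.csv")))
})

test_that("failures leave no partial outputs behind", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Year,Count,Population", "1999,5,1000", "2000,Suppressed,1000"),
             f)
  out <- tempfile("rtfail")
  cfg <- run_config(input = f, chains = 2, draws = 300, warmup = 100,
                    out = out)
  expect_error(run_surveillance(cfg, quiet = TRUE), "suppressed")
  expect_equal(length(list.files(out)), 0L)
})
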