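test_that("generation is deterministic given the seed", {
  cfg <- quick_config(seed = 11)
  expect_identical(simulate_city(cfg), simulate_city(cfg))
})

test_that("full coverage means reported deaths equal true deaths", {
  cfg <- quick_config(seed = 12, coverage_base = 1, coverage_ses_slope = 0)
  sim <- simulate_city(cfg)
  expect_identical(sim$deaths_reported$deaths, sim$deaths_true$deaths)
  expect_true(all(sim$truth$true_coverage == 1))
})

test_that("reported/true death ratio tracks the unit's true coverage", {
  cfg <- city_config(n_units = 12, population_scale = 1e5, seed = 13,
                     coverage_base = 0.8, coverage_ses_slope = 2)
  sim <- simulate_city(cfg)
  obs <- dplyr::inner_join(
    dplyr::count(sim$deaths_reported, unit_id, sex, wt = deaths, name = "rep"),
    dplyr::count(sim$deaths_true, unit_id, sex, wt = deaths, name = "true"),
    by = c("unit_id", "sex")
  )
  obs <- dplyr::inner_join(obs, sim$truth, by = c("unit_id", "sex"))
  expect_true(all(abs(obs$rep / obs$true - obs$true_coverage) < 0.03))
})

test_that("with no SES effect or age deviations, units share one schedule and crude rates scatter as Poisson", {
  cfg <- city_config(n_units = 40, population_scale = 5e4, seed = 14,
                     ses_beta = 0, ar_sigma = 0, coverage_base = 1,
                     coverage_ses_slope = 0)
  sim <- simulate_city(cfg)
  rates <- tidyr::pivot_wider(sim$truth_rates, id_cols = c(unit_id, sex),
                              names_from = age_lower, values_from = true_rate)
  for (s in c("male", "female")) {
    sub <- as.matrix(rates[rates$sex == s, -(1:2)])
    expect_lt(max(apply(sub, 2, sd)), 1e-12)  # one shared schedule
  }
  # chi-square goodness of fit: total observed deaths per unit vs expected
  d <- dplyr::count(sim$deaths_true, unit_id, sex, age_lower,
                    wt = deaths, name = "obs")
  py <- dplyr::count(sim$population[sim$population$year < max(sim$population$year), ],
                     unit_id, sex, age_lower, wt = population, name = "py")
  d <- dplyr::inner_join(d, py, by = c("unit_id", "sex", "age_lower"))
  d <- dplyr::inner_join(d, sim$truth_rates, by = c("unit_id", "sex", "age_lower"))
  d$expected <- d$true_rate * d$py
  d <- d[d$expected > 20, ]
  x2 <- sum((d$obs - d$expected)^2 / d$expected)
  # Poisson variance: X2 ~ chi-square with one df per cell
  expect_gt(stats::pchisq(x2, df = nrow(d)), 1e-4)
  expect_lt(stats::pchisq(x2, df = nrow(d)), 1 - 1e-4)
})

test_that("age-group deviations have the configured AR(1) autocorrelation", {
  cfg <- city_config(n_units = 300, population_scale = 1e4, seed = 15,
                     ar_rho = 0.8, ar_sigma = 0.4, ses_beta = 0)
  sim <- simulate_city(cfg)
  sch <- sim$scheme
  base_log <- log(cfg$makeham_C + cfg$gompertz_A * exp(cfg$gompertz_B * sch$midpoints))
  th <- sim$truth_rates[sim$truth_rates$sex == "female", ]
  th <- tidyr::pivot_wider(th, id_cols = unit_id, names_from = age_lower,
                           values_from = true_rate)
  mat <- log(as.matrix(th[, -1]))
  mat <- sweep(mat, 2, base_log)          # remove age curve; SES is off
  A <- ncol(mat)
  # pooled lag-1 autocorrelation across units (mean-zero by construction)
  l1 <- cor(as.vector(mat[, -1]), as.vector(mat[, -A]))
  expect_lt(abs(l1 - cfg$ar_rho), 0.05)
})

test_that("stationary fixture is demographically consistent", {
  # r = 0 and a pure constant hazard: age density proportional to exp(-mu x)
  cfg <- city_config(seed = 16, gompertz_A = 1e-12, gompertz_B = 0,
                     makeham_C = 0.02, growth_rate = 0)
  st <- simulate_stationary_population(cfg)
  sch <- st$scheme
  closed <- seq_len(n_groups(sch) - 1)
  expected <- exp(-0.02 * sch$lower[closed]) * (1 - exp(-0.02 * 5))
  ratio <- st$pop_t1[closed] / expected
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)

  # growth: population at t2 is exp(r * window) times t1 in every group
  cfg2 <- city_config(seed = 17, growth_rate = 0.015)
  st2 <- simulate_stationary_population(cfg2)
  expect_equal(st2$pop_t2, st2$pop_t1 * exp(0.015 * st2$window))

  # long tables match the group vectors
  expect_equal(sum(st2$deaths$deaths), sum(st2$deaths_annual) * st2$window)
})

test_that("degenerate configs are rejected", {
  expect_error(city_config(n_units = 1))
  expect_error(city_config(ar_rho = 1))
  expect_error(city_config(coverage_base = 0))
})

test_that("write_city_sim emits the four CSVs that the readers accept", {
  sim <- simulate_city(quick_config(seed = 18))
  dir <- withr::local_tempdir()
  write_city_sim(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("deaths.csv", "population.csv",
                                               "units.csv", "truth.csv")))))
  back <- read_death_table(file.path(dir, "deaths.csv"))
  expect_equal(sum(back$deaths), sum(sim$deaths_reported$deaths))
  expect_silent(read_unit_attributes(file.path(dir, "units.csv")))
})
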