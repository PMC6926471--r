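test_that("a dominant unit's posterior rates sit on its crude rates", {
  # huge person-years: the likelihood overwhelms prior and shrinkage
  sch <- age_scheme()
  set.seed(41)
  true_rate <- 3e-5 * exp(0.095 * sch$midpoints) + 5e-4
  grid <- tidyr::expand_grid(unit_id = c("big", "tiny"), sex = "female",
                             age_lower = sch$lower, year = 2011L)
  py <- ifelse(grid$unit_id == "big", 1e7, 1e3)
  deaths <- grid
  deaths$deaths <- rpois(nrow(grid), true_rate[match(grid$age_lower, sch$lower)] * py)
  population <- grid
  population$population <- py
  fit <- suppressWarnings(
    fit_smoothing_model(deaths, population, quick_smoothing(seed = 42)))
  crude_big <- deaths$deaths[deaths$unit_id == "big"] /
    population$population[population$unit_id == "big"]
  post_big <- apply(fit$draws[, "big", ], 2, mean)
  expect_true(all(abs(post_big / crude_big - 1) < 0.02))
})

test_that("zero-death strata shrink toward the city age curve, staying positive", {
  sch <- age_scheme()
  set.seed(43)
  true_rate <- 3e-5 * exp(0.095 * sch$midpoints) + 5e-4
  grid <- tidyr::expand_grid(unit_id = sprintf("u%02d", 1:6), sex = "male",
                             age_lower = sch$lower, year = 2011L)
  py <- ifelse(grid$unit_id == "u01", 50, 2e5)  # u01 tiny: expect 0 deaths young
  deaths <- grid
  deaths$deaths <- rpois(nrow(grid), true_rate[match(grid$age_lower, sch$lower)] * py)
  deaths$deaths[deaths$unit_id == "u01"] <- 0
  population <- grid; population$population <- py
  fit <- suppressWarnings(
    fit_smoothing_model(deaths, population, quick_smoothing(seed = 44)))
  post_u1 <- apply(fit$draws[, "u01", ], 2, mean)
  expect_true(all(post_u1 > 0))
  # shrinks to within a factor ~2 of the city curve despite zero deaths
  city_curve <- apply(fit$draws, 3, mean)
  expect_true(all(abs(log(post_u1) - log(city_curve)) < log(3)))
})

test_that("posterior_summary matches a brute-force sort-based quantile", {
  sch <- age_scheme()
  sim <- simulate_city(quick_config(seed = 45))
  d <- sim$deaths_reported[sim$deaths_reported$sex == "female", ]
  fit <- suppressWarnings(
    fit_smoothing_model(d, sim$population, quick_smoothing(seed = 46)))
  s <- posterior_summary(fit)
  u <- fit$unit_ids[2]; ai <- 4
  v <- sort(fit$draws[, 2, 4])
  row <- s[s$unit_id == u & s$age_lower == sch$lower[ai], ]
  expect_equal(row$rate_median, unname(quantile(v, 0.5)))
  expect_equal(row$rate_lo95, unname(quantile(v, 0.025)))
  expect_equal(row$rate_hi95, unname(quantile(v, 0.975)))
  # tidy() round-trips the draw array
  td <- tidy(fit)
  expect_equal(nrow(td), prod(dim(fit$draws)))
  expect_equal(td$rate[td$unit_id == u & td$age_lower == sch$lower[ai]],
               fit$draws[, 2, 4])
})

test_that("AR(1) hyperparameters are recovered from data generated with them", {
  # moderate-size recovery check; the acceptance suite runs replicates
  cfg <- city_config(n_units = 20, population_scale = 3e4, seed = 47,
                     ar_rho = 0.8, ar_sigma = 0.5, coverage_base = 1,
                     coverage_ses_slope = 0, ses_beta = 0)
  sim <- simulate_city(cfg)
  d <- sim$deaths_true[sim$deaths_true$sex == "female", ]
  fit <- fit_smoothing_model(d, sim$population,
                             smoothing_config(burn_in = 1000, iterations = 2000,
                                              n_draws = 500, chains = 2,
                                              seed = 48))
  expect_lt(max(fit$diagnostics$rhat, na.rm = TRUE), 1.1)
  rho_ci <- quantile(fit$hyper$rho, c(0.025, 0.975))
  sig_ci <- quantile(fit$hyper$sigma, c(0.025, 0.975))
  expect_lt(abs(mean(fit$hyper$rho) - 0.8), 0.2)
  expect_lt(abs(mean(fit$hyper$sigma) - 0.5), 0.2)
})

test_that("non-integer corrected counts are accepted by both likelihood modes", {
  tt <- toy_tables()
  d <- tt$deaths[tt$deaths$sex == "female", ]
  d$deaths <- d$deaths + 0.37
  p <- tt$population
  cfgs <- list(quick_smoothing(seed = 49),
               quick_smoothing(seed = 49, rounding = "stochastic"))
  for (cfg in cfgs) {
    fit <- suppressWarnings(fit_smoothing_model(d, p, cfg))
    expect_true(all(fit$draws > 0))
    expect_equal(dim(fit$draws), c(200, 2, 16))
  }
})

test_that("permuting unit labels permutes outputs identically", {
  sim <- simulate_city(quick_config(seed = 50))
  d <- sim$deaths_reported[sim$deaths_reported$sex == "male", ]
  p <- sim$population
  fit1 <- suppressWarnings(fit_smoothing_model(d, p, quick_smoothing(seed = 51)))
  relabel <- setNames(sprintf("z%02d", seq_along(fit1$unit_ids)), fit1$unit_ids)
  d2 <- d; d2$unit_id <- unname(relabel[d2$unit_id])
  p2 <- p; p2$unit_id <- unname(relabel[p2$unit_id])
  fit2 <- suppressWarnings(fit_smoothing_model(d2, p2, quick_smoothing(seed = 51)))
  # same ordering after relabelling (z order follows original order)
  expect_equal(fit2$draws[, , ], fit1$draws[, , ], ignore_attr = TRUE)
})

test_that("too-short chains trigger the convergence warning, with diagnostics attached", {
  sim <- simulate_city(quick_config(seed = 52))
  d <- sim$deaths_reported[sim$deaths_reported$sex == "female", ]
  expect_warning(
    fit <- fit_smoothing_model(d, sim$population,
                               smoothing_config(burn_in = 10, iterations = 40,
                                                n_draws = 20, chains = 2,
                                                seed = 53)),
    "Rhat"
  )
  expect_true(all(c("param", "rhat", "ess") %in% names(fit$diagnostics)))
})
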