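test_that("Gompertz fit is exact on exact log-linear input and matches a grid search on noise", {
  sch <- age_scheme()
  A0 <- 4e-5; B0 <- 0.09
  rates <- A0 * exp(B0 * sch$midpoints)
  f <- fit_gompertz(rates, sch)
  expect_equal(f$A, A0, tolerance = 1e-12)
  expect_equal(f$B, B0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  # constant rates: B = 0, A = the rate
  fc <- fit_gompertz(rep(0.02, n_groups(sch)), sch)
  expect_equal(fc$B, 0, tolerance = 1e-12)
  expect_equal(fc$A, 0.02, tolerance = 1e-12)

  # noisy schedule vs brute-force grid search over (log A, B)
  set.seed(31)
  noisy <- rates * exp(rnorm(length(rates), 0, 0.1))
  fn <- fit_gompertz(noisy, sch)
  sel <- sch$lower >= 45 & sch$lower <= 70
  obj <- function(logA, B) {
    sum((log(noisy[sel]) - (logA + B * sch$midpoints[sel]))^2)
  }
  grid <- tidyr::expand_grid(logA = log(fn$A) + seq(-0.2, 0.2, length.out = 81),
                             B = fn$B + seq(-0.02, 0.02, length.out = 81))
  vals <- mapply(obj, grid$logA, grid$B)
  best <- grid[which.min(vals), ]
  expect_equal(log(fn$A), best$logA, tolerance = 1e-8)
  expect_equal(fn$B, best$B, tolerance = 1e-8)
  zeroed <- rates
  zeroed[sch$lower == 50] <- 0
  expect_error(fit_gompertz(zeroed, sch), "non-positive")
})

test_that("extrapolation keeps observed rates and appends Gompertz predictions", {
  sch <- age_scheme()
  A0 <- 3e-5; B0 <- 0.1
  rates <- A0 * exp(B0 * sch$midpoints)
  f <- fit_gompertz(rates, sch)
  ext <- extrapolate_rates(rates, f, sch)
  expect_equal(ext$lower, c(seq(0, 70, 5), seq(75, 105, 5)))
  mids <- c(head(sch$midpoints, -1), seq(77.5, 102.5, 5), 107.5)
  expect_equal(ext$rate, A0 * exp(B0 * mids), tolerance = 1e-10)
  expect_true(all(diff(ext$rate) > 0))  # monotone when B > 0
})

test_that("life table closed forms and invariants hold", {
  sch <- age_scheme()
  # zero mortality below 75, open-interval m = 0.1 -> e0 = 75 + 10
  lt <- build_life_table(c(rep(0, 15), 0.1), sch$lower)
  expect_equal(lt$e[1], 85)
  expect_equal(life_expectancy_at(lt, 40), 45)
  expect_equal(life_expectancy_at(lt, 0), lt$e[1])
  expect_error(life_expectancy_at(lt, 42), "boundary")

  # conservation: total deaths = radix; T(0) = sum of L
  rates <- 5e-5 * exp(0.09 * sch$midpoints) + 1e-3
  lt2 <- build_life_table(rates, sch$lower)
  expect_equal(sum(lt2$d), 1e5)
  expect_equal(lt2$T[1], sum(lt2$L))
  expect_true(all(diff(lt2$l) <= 0))
  # radix invariance
  lt3 <- build_life_table(rates, sch$lower, radix = 1)
  expect_equal(lt3$e, lt2$e, tolerance = 1e-12)
  # doubling mortality strictly decreases e0
  expect_lt(build_life_table(rates * 2, sch$lower)$e[1], lt2$e[1])
  expect_error(build_life_table(c(rates[-16], 0), sch$lower), "open-interval")
})

test_that("e0 matches a piecewise-constant-hazard microsimulation", {
  sch <- age_scheme()
  set.seed(32)
  for (r in 1:3) {
    rates <- (3e-5 * exp(0.095 * sch$midpoints) + 5e-4) *
      exp(rnorm(16, 0, 0.15))
    f <- fit_gompertz(rates, sch)
    ext <- extrapolate_rates(rates, f, sch)
    lt <- build_life_table(ext$rate, ext$lower, a_first = 2.5)
    mc <- simulate_mean_lifetime(ext$rate, ext$lower, n = 1e6, seed = 320 + r)
    # a = n/2 everywhere in the oracle, so compare with a_first = 2.5
    expect_lt(abs(lt$e[1] - mc), 0.1)
  }
})

test_that("e40/e60 match the microsimulation's mean residual lifetime", {
  sch <- age_scheme()
  rates <- 4e-5 * exp(0.09 * sch$midpoints) + 8e-4
  f <- fit_gompertz(rates, sch)
  ext <- extrapolate_rates(rates, f, sch)
  lt <- build_life_table(ext$rate, ext$lower)
  set.seed(33)
  n <- 1e6
  K <- length(ext$rate)
  width <- c(diff(ext$lower), Inf)
  cumhaz <- c(0, cumsum(ext$rate[-K] * width[-K]))
  for (age in c(40, 60)) {
    # residual lifetime: condition the hazard on survival to `age`
    h0 <- cumhaz[match(age, ext$lower)]
    u <- stats::rexp(n) + h0
    idx <- findInterval(u, cumhaz)
    death_age <- ext$lower[idx] + (u - cumhaz[idx]) / ext$rate[idx]
    expect_lt(abs(life_expectancy_at(lt, age) - mean(death_age - age)), 0.1)
  }
})

test_that("extrapolated e0 agrees with the integrated Gompertz survival curve", {
  sch <- age_scheme()
  A0 <- 2.5e-5; B0 <- 0.1
  rates <- A0 * exp(B0 * sch$midpoints)
  f <- fit_gompertz(rates, sch)
  ext <- extrapolate_rates(rates, f, sch)
  lt <- build_life_table(ext$rate, ext$lower, a_first = 2.5)
  # numerical integration of S(x) = exp(-A/B (e^{Bx} - 1))
  x <- seq(0, 130, by = 0.01)
  S <- exp(-A0 / B0 * (exp(B0 * x) - 1))
  e0_int <- sum((head(S, -1) + tail(S, -1)) / 2 * 0.01)
  expect_lt(abs(lt$e[1] - e0_int), 0.2)
})

test_that("constant-hazard limit: e0 approaches 1/mu when the open interval dominates", {
  mu <- 0.05  # most person-years fall in the open interval
  lower <- c(0, 5)
  lt <- build_life_table(c(mu, mu), lower, a_first = 2.5)
  expect_lt(abs(lt$e[1] - 1 / mu), 0.05)
})

test_that("e0_draws summarises identical draws to their common value", {
  sch <- age_scheme()
  rates <- 3e-5 * exp(0.095 * sch$midpoints) + 5e-4
  draws <- tidyr::expand_grid(draw = 1:5, unit_id = "u1", sex = "female",
                              age_lower = sch$lower)
  draws$rate <- rep(rates, times = 5)
  e <- e0_draws(draws)
  expect_equal(length(unique(round(e$e0, 10))), 1)
  s <- life_expectancy_summary(e)
  expect_equal(s$e0_median, e$e0[1])
  expect_equal(s$e0_hi95 - s$e0_lo95, 0)
})
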