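# Shared fixtures: small, fast configs built in code.

quick_config <- function(seed = 1L, ...) {
  city_config(n_units = 8, population_scale = 2e4, seed = seed, ...)
}

quick_smoothing <- function(seed = 1L, ...) {
  smoothing_config(burn_in = 500, iterations = 1000, n_draws = 200,
                   chains = 2, seed = seed, ...)
}

# Deaths/population tables for a hand-built two-unit toy city.
toy_tables <- function(scheme = age_scheme()) {
  grid <- tidyr::expand_grid(unit_id = c("u1", "u2"), sex = SEXES,
                             age_lower = scheme$lower, year = 2011:2015)
  grid <- grid[order(grid$unit_id, grid$sex, grid$age_lower, grid$year), ]
  deaths <- grid
  deaths$deaths <- 10
  population <- grid
  population$population <- 1000
  list(deaths = deaths, population = population)
}

# Monte-Carlo oracle: mean lifetime under a piecewise-constant hazard,
# simulated by inverse-CDF sampling of the death age.
simulate_mean_lifetime <- function(rates, lower, n = 1e5, seed = 1) {
  set.seed(seed)
  K <- length(rates)
  width <- c(diff(lower), Inf)
  cumhaz <- c(0, cumsum(rates[-K] * width[-K]))
  u <- stats::rexp(n)  # total hazard at death
  idx <- findInterval(u, cumhaz)
  age <- lower[idx] + (u - cumhaz[idx]) / rates[idx]
  mean(age)
}

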