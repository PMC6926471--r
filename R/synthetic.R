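#' Configuration for the synthetic multi-city generator
#'
#' The generator emulates the data structure the pipeline consumes: subcity
#' units with death and population counts by sex, 5-year age group and
#' year, plus unit-level attributes. Mortality follows a Gompertz-Makeham
#' baseline hazard shifted multiplicatively by unit socioeconomic status
#' (education), with mean-zero stationary AR(1) deviations across age
#' groups, SES-linked death-registration undercounting, and exponential
#' population growth.
#'
#' @param n_units Number of subcity units (>= 2).
#' @param years Length of the analysis window in calendar years.
#' @param year0 First calendar year of the window.
#' @param population_scale Median unit population (persons; unit totals are
#'   lognormal around this).
#' @param population_sdlog Log-scale SD of unit populations.
#' @param education_dist Beta shape parameters `c(shape1, shape2)` for the
#'   unit-level proportion of adults with completed secondary education.
#' @param gompertz_A Baseline Gompertz hazard level at age 0 (per
#'   person-year).
#' @param gompertz_B Gompertz log-hazard slope per year of age.
#' @param makeham_C Age-constant (Makeham) hazard component.
#' @param ses_beta Change in log hazard per unit of education (negative =
#'   protective).
#' @param sex_log_hr Additive male excess on the log hazard (applied to
#'   males only).
#' @param ar_rho AR(1) correlation of the age-group deviations, |rho| < 1.
#' @param ar_sigma Innovation SD of the AR(1) log-rate deviations.
#' @param coverage_base Baseline death-registration coverage (proportion).
#' @param coverage_ses_slope Change in logit coverage per unit of
#'   (centred) education; positive means richer units register better.
#' @param growth_rate Annual exponential population growth rate.
#' @param seed Integer seed; one shared random stream drives every draw.
#' @return A list of class `city_config`.
#' @export
city_config <- function(n_units = 20,
                        years = 5,
                        year0 = 2011,
                        population_scale = 5e4,
                        population_sdlog = 0.5,
                        education_dist = c(3.5, 6),
                        gompertz_A = 3e-5,
                        gompertz_B = 0.095,
                        makeham_C = 5e-4,
                        ses_beta = -0.6,
                        sex_log_hr = 0.3,
                        ar_rho = 0.8,
                        ar_sigma = 0.15,
                        coverage_base = 0.9,
                        coverage_ses_slope = 2,
                        growth_rate = 0.01,
                        seed = 1L) {
  stopifnot(
    n_units >= 2, years >= 1,
    gompertz_A > 0, gompertz_B >= 0, makeham_C >= 0,
    abs(ar_rho) < 1, ar_sigma >= 0,
    coverage_base > 0, coverage_base <= 1
  )
  structure(as.list(environment()), class = "city_config")
}

# Gompertz-Makeham hazard.
gm_hazard <- function(x, A, B, C) C + A * exp(B * x)

# Stable-population age density n(x) ~ exp(-r x) * l(x) on a fine grid.
# Returns grid ages, density (unnormalised), survival and hazard.
stable_grid <- function(A, B, C, r, dx = 0.1, max_age = 120) {
  x <- seq(0, max_age, by = dx)
  mu <- gm_hazard(x, A, B, C)
  H <- c(0, cumsum((head(mu, -1) + tail(mu, -1)) / 2 * dx))  # trapezoid
  lx <- exp(-H)
  list(x = x, dens = exp(-r * x) * lx, lx = lx, mu = mu)
}

# Stable age structure implied by a group-wise constant hazard schedule and
# growth rate r: person-years per group of exp(-r x) l(x), normalised.
stable_structure_from_rates <- function(rates, scheme, r) {
  K <- length(rates)
  w <- scheme$width
  l <- cumprod(c(1, exp(-w * rates[-K])))
  x0 <- scheme$lower
  g <- r + rates
  closed <- exp(-r * x0[-K]) * l[-K] * (1 - exp(-w * g[-K])) / g[-K]
  open <- exp(-r * x0[K]) * l[K] / g[K]
  s <- c(closed, open)
  s / sum(s)
}

# Aggregate a fine-grid quantity into scheme age groups (open last group).
grid_to_groups <- function(x, values, scheme, dx) {
  lower <- scheme$lower
  upper <- c(tail(lower, -1), Inf)
  vapply(seq_along(lower), function(i) {
    sum(values[x >= lower[i] & x < upper[i]]) * dx
  }, numeric(1))
}

#' Simulate one synthetic city
#'
#' Draws unit attributes, true and reported death counts, and population
#' series for one city under the generative model described in
#' [city_config()]. The truth record stores each unit's true age-specific
#' rate schedule, true life expectancy at birth (the abridged life-table
#' functional of the true rates, using the package's Gompertz extension
#' convention), and true registration coverage.
#'
#' @param config A [city_config()].
#' @param city_id City identifier used in unit attributes.
#' @param scheme An [age_scheme()].
#' @return A list of class `city_sim` with elements `deaths_true`,
#'   `deaths_reported`, `population` (tibbles in the standard long
#'   format; population includes one extra trailing year), `units`
#'   (attributes tibble), `truth` (tibble: unit_id, sex, true_e0,
#'   true_coverage) and `truth_rates` (tibble: unit_id, sex, age_lower,
#'   true_rate).
#' @export
simulate_city <- function(config, city_id = "city1", scheme = age_scheme()) {
  stopifnot(inherits(config, "city_config"))
  cf <- config
  if (cf$n_units < 2) abort("need at least 2 units")
  set.seed(cf$seed)

  U <- cf$n_units
  A <- n_groups(scheme)
  unit_id <- sprintf("%s_u%02d", city_id, seq_len(U))

  education <- rbeta(U, cf$education_dist[1], cf$education_dist[2])
  edu_c <- education - mean(education)

  units <- tibble::tibble(
    unit_id = unit_id,
    city_id = city_id,
    education = education,
    water = plogis(qlogis(0.85) + 1.5 * edu_c + rnorm(U, 0, 0.3)),
    overcrowding = plogis(qlogis(0.15) - 2 * edu_c + rnorm(U, 0, 0.3)),
    builtup = rbeta(U, 5, 2),
    lon = rnorm(U, 0, 0.15),
    lat = rnorm(U, 0, 0.15)
  )

  # Unit population totals; each unit x sex gets the stable age structure
  # of its own hazard so deaths and populations are demographically
  # consistent (the balance the death-distribution methods assume).
  unit_pop <- rlnorm(U, log(cf$population_scale), cf$population_sdlog)

  # True rate schedules: baseline + SES shift + AR(1) age deviations,
  # per unit x sex.
  base_log <- log(gm_hazard(scheme$midpoints, cf$gompertz_A, cf$gompertz_B,
                            cf$makeham_C))
  years_seq <- cf$year0 + seq_len(cf$years) - 1L
  pop_years <- c(years_seq, max(years_seq) + 1L)  # extra trailing year

  truth_rates <- list(); truth <- list()
  deaths_true <- list(); deaths_rep <- list(); pops <- list()
  k <- 0L
  for (s in SEXES) {
    sex_shift <- if (s == "male") cf$sex_log_hr else 0
    # stationary AR(1) deviations, one series per unit
    theta <- matrix(0, U, A)
    if (cf$ar_sigma > 0) {
      theta[, 1] <- rnorm(U, 0, cf$ar_sigma / sqrt(1 - cf$ar_rho^2))
      for (a in 2:A) {
        theta[, a] <- cf$ar_rho * theta[, a - 1] + rnorm(U, 0, cf$ar_sigma)
      }
    }
    log_rate <- sweep(theta, 2, base_log + sex_shift, "+") +
      matrix(cf$ses_beta * edu_c, U, A)
    rate <- exp(log_rate)

    cov_u <- plogis(qlogis(cf$coverage_base) + cf$coverage_ses_slope * edu_c)
    cov_u <- pmin(cov_u, 1)

    for (u in seq_len(U)) {
      k <- k + 1L
      age_struct <- stable_structure_from_rates(rate[u, ], scheme,
                                                cf$growth_rate)
      pop_u_sex <- unit_pop[u] * 0.5 * age_struct  # equal sex split
      for (yi in seq_along(pop_years)) {
        y <- pop_years[yi]
        pop_y <- pop_u_sex * exp(cf$growth_rate * (yi - 1))
        pops[[length(pops) + 1L]] <- tibble::tibble(
          unit_id = unit_id[u], sex = s, age_lower = scheme$lower,
          year = y, population = pop_y
        )
        if (y %in% years_seq) {
          dt <- rpois(A, rate[u, ] * pop_y)
          dr <- rbinom(A, dt, cov_u[u])
          deaths_true[[length(deaths_true) + 1L]] <- tibble::tibble(
            unit_id = unit_id[u], sex = s, age_lower = scheme$lower,
            year = y, deaths = as.numeric(dt)
          )
          deaths_rep[[length(deaths_rep) + 1L]] <- tibble::tibble(
            unit_id = unit_id[u], sex = s, age_lower = scheme$lower,
            year = y, deaths = as.numeric(dr)
          )
        }
      }
      fit <- fit_gompertz(rate[u, ], scheme)
      ext <- extrapolate_rates(rate[u, ], fit, scheme)
      lt <- build_life_table(ext$rate, ext$lower)
      truth[[k]] <- tibble::tibble(
        unit_id = unit_id[u], sex = s,
        true_e0 = lt$e[1], true_coverage = cov_u[u]
      )
      truth_rates[[k]] <- tibble::tibble(
        unit_id = unit_id[u], sex = s, age_lower = scheme$lower,
        true_rate = rate[u, ]
      )
    }
  }

  structure(list(
    deaths_true = dplyr::bind_rows(deaths_true),
    deaths_reported = dplyr::bind_rows(deaths_rep),
    population = dplyr::bind_rows(pops),
    units = units,
    truth = dplyr::bind_rows(truth),
    truth_rates = dplyr::bind_rows(truth_rates),
    config = cf, scheme = scheme
  ), class = "city_sim")
}

#' Simulate several cities into one bundle
#'
#' Calls [simulate_city()] once per city with derived seeds and binds the
#' tables. `...` overrides [city_config()] defaults shared by all cities;
#' per-city variation can be injected through `tweak`, a function
#' `(config, city_index) -> config`.
#'
#' @param n_cities Number of cities.
#' @param seed Master seed; city seeds are derived from it.
#' @param tweak Optional function modifying each city's config.
#' @param ... Passed to [city_config()].
#' @return A list of class `city_sim` with the same elements as
#'   [simulate_city()], units spanning all cities.
#' @export
simulate_cities <- function(n_cities = 2, seed = 1L, tweak = NULL, ...) {
  sims <- lapply(seq_len(n_cities), function(i) {
    cf <- city_config(..., seed = (seed * 1000L + i) %% .Machine$integer.max)
    if (!is.null(tweak)) cf <- tweak(cf, i)
    simulate_city(cf, city_id = sprintf("city%d", i))
  })
  structure(list(
    deaths_true = dplyr::bind_rows(lapply(sims, `[[`, "deaths_true")),
    deaths_reported = dplyr::bind_rows(lapply(sims, `[[`, "deaths_reported")),
    population = dplyr::bind_rows(lapply(sims, `[[`, "population")),
    units = dplyr::bind_rows(lapply(sims, `[[`, "units")),
    truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")),
    truth_rates = dplyr::bind_rows(lapply(sims, `[[`, "truth_rates")),
    config = sims[[1]]$config, scheme = sims[[1]]$scheme
  ), class = "city_sim")
}

#' Deterministic stationary-population fixture
#'
#' Builds a demographically consistent stable population under a
#' Gompertz-Makeham hazard and exponential growth: age density
#' proportional to `exp(-r x) * l(x)`, deaths consistent with the hazard,
#' populations at two time points `window` years apart. Counts are
#' expected values (no sampling noise), which makes the fixture suitable
#' for exact-recovery tests of the death-distribution methods.
#'
#' @param config A [city_config()]; only the hazard, growth and scale
#'   fields are used.
#' @param window Years between the two population time points (also the
#'   death window).
#' @param scheme An [age_scheme()].
#' @return A list with `deaths` (mean annual deaths by group at the window
#'   midpoint, long tibble over `window` identical years), `population`
#'   (long tibble for the first and last year), and the per-group vectors
#'   `pop_t1`, `pop_t2`, `deaths_annual` used by [ggb_coverage()] /
#'   [seg_coverage()].
#' @export
simulate_stationary_population <- function(config, window = 5,
                                           scheme = age_scheme()) {
  stopifnot(inherits(config, "city_config"))
  cf <- config
  grid <- stable_grid(cf$gompertz_A, cf$gompertz_B, cf$makeham_C,
                      cf$growth_rate, dx = 0.05)
  dens <- grid$dens
  scale <- cf$population_scale / (sum(dens) * 0.05)
  dens <- dens * scale
  pop_t1 <- grid_to_groups(grid$x, dens, scheme, 0.05)
  pop_t2 <- pop_t1 * exp(cf$growth_rate * window)
  # annual deaths at window midpoint: density * hazard, grown to midpoint
  d_dens <- dens * grid$mu * exp(cf$growth_rate * window / 2)
  deaths_annual <- grid_to_groups(grid$x, d_dens, scheme, 0.05)

  years <- cf$year0 + seq_len(window) - 1L
  deaths <- dplyr::bind_rows(lapply(years, function(y) {
    tibble::tibble(unit_id = "stationary", sex = "female",
                   age_lower = scheme$lower, year = y,
                   deaths = deaths_annual)
  }))
  population <- dplyr::bind_rows(
    tibble::tibble(unit_id = "stationary", sex = "female",
                   age_lower = scheme$lower, year = years[1],
                   population = pop_t1),
    tibble::tibble(unit_id = "stationary", sex = "female",
                   age_lower = scheme$lower, year = years[1] + window,
                   population = pop_t2)
  )
  list(deaths = deaths, population = population,
       pop_t1 = pop_t1, pop_t2 = pop_t2, deaths_annual = deaths_annual,
       scheme = scheme, window = window)
}

#' Write a simulated bundle to CSV files
#'
#' Emits `deaths.csv` (reported counts), `population.csv`, `units.csv`
#' and `truth.csv` into a directory, matching the reader contracts.
#'
#' @param sim A `city_sim` from [simulate_city()] or [simulate_cities()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_city_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "city_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$deaths_reported, file.path(dir, "deaths.csv"), progress = FALSE)
  readr::write_csv(sim$population, file.path(dir, "population.csv"), progress = FALSE)
  units <- sim$units[, c("unit_id", "city_id", "education", "water",
                         "overcrowding", "builtup", "lon", "lat")]
  readr::write_csv(units, file.path(dir, "units.csv"), progress = FALSE)
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), progress = FALSE)
  invisible(dir)
}

#' @importFrom stats plogis qlogis
NULL
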