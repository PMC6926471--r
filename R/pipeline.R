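#' Pipeline configuration
#'
#' Bundles every analytical choice of the end-to-end run. The three
#' `undercount_mode` values correspond to the main analysis and two
#' sensitivity analyses: `"correct"` inflates deaths by 1/coverage
#' (truncated at 1); `"drop_below_0.9"` keeps only units with truncated
#' coverage >= 0.9 and applies no correction; `"no_truncation"` corrects
#' with the raw (untruncated) harmonic-mean coverage.
#'
#' @param deaths,population,units File paths (CSV) or in-memory tibbles.
#' @param scheme An [age_scheme()].
#' @param undercount_mode See above.
#' @param fit_range DDM cutoff-age interval.
#' @param smoothing A [smoothing_config()].
#' @param a_first,extend_to,gompertz_fit_ages Life-table options.
#' @param outcome_age 0, 40 or 60 (sensitivity outcomes).
#' @param exposure `"education"`, `"water"` or `"overcrowding"`.
#' @param spatial_adjust Spatial-polynomial sensitivity flag.
#' @param weighted_quantiles Use population weights in the within-city
#'   decile computations.
#' @param seed Integer seed for the run.
#' @param outdir Output directory for the report tables, or `NULL` to
#'   skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(deaths, population, units,
                            scheme = age_scheme(),
                            undercount_mode = c("correct", "drop_below_0.9",
                                                "no_truncation"),
                            fit_range = c(15, 65),
                            smoothing = smoothing_config(),
                            a_first = 1.0, extend_to = 105,
                            gompertz_fit_ages = c(45, 70),
                            outcome_age = 0,
                            exposure = "education",
                            spatial_adjust = FALSE,
                            weighted_quantiles = TRUE,
                            seed = 1L, outdir = NULL) {
  undercount_mode <- match.arg(undercount_mode)
  stopifnot(outcome_age %in% c(0, 40, 60))
  structure(as.list(environment()), class = "pipeline_config")
}

load_table <- function(x, reader, scheme) {
  if (is.character(x)) {
    if (!file.exists(x)) abort(sprintf("input file not found: %s", x))
    reader(x, scheme)
  } else {
    x
  }
}

#' Run the full pipeline
#'
#' Ingest, coverage estimation, undercount correction, Bayesian rate
#' smoothing per city x sex, life-table construction per posterior draw,
#' within-city inequality summaries, between/within-city variance
#' decomposition, and the Rubin-pooled SES association — in one call.
#' Each stage's output is returned and (when `outdir` is set) written as
#' CSV: `coverage.csv`, `life_expectancy.csv`, `inequality.csv`,
#' `icc.csv`, `association.csv`, plus a `manifest.json` echoing the
#' configuration, seed, timings and warnings.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_bundle` with elements `coverage`,
#'   `life_expectancy`, `e0_draws`, `inequality`, `icc`, `association`,
#'   `units`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  t0 <- Sys.time()
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  scheme <- cf$scheme
  deaths <- load_table(cf$deaths, read_death_table, scheme)
  deaths <- validate_death_table(deaths, scheme)
  population <- load_table(cf$population, read_population_table, scheme)
  population <- validate_population_table(population, scheme, deaths)
  units <- if (is.character(cf$units)) read_unit_attributes(cf$units) else
    validate_unit_attributes(cf$units)
  death_years <- sort(unique(deaths$year))
  units <- add_mean_population(units, population, years = death_years)

  ## stage: coverage
  stage <- "coverage"
  coverage <- withCallingHandlers(
    tryCatch(
      estimate_coverage(deaths, population, units, scheme, cf$fit_range,
                        truncate = TRUE),
      error = function(e) abort(sprintf("stage %s failed: %s", stage,
                                        conditionMessage(e)))
    ), warning = log_warning)

  ## stage: correction / unit selection
  if (cf$undercount_mode == "correct") {
    deaths_c <- correct_deaths(deaths, coverage, column = "truncated")
  } else if (cf$undercount_mode == "no_truncation") {
    deaths_c <- correct_deaths(deaths, coverage, column = "combined")
  } else {
    keep <- coverage[coverage$truncated >= 0.9, c("unit_id", "sex")]
    deaths_c <- dplyr::semi_join(deaths, keep, by = c("unit_id", "sex"))
    if (!nrow(deaths_c)) abort("stage correction failed: no unit has coverage >= 0.9")
  }

  ## stage: smoothing + life tables, per city x sex
  city_of <- setNames(units$city_id, units$unit_id)
  deaths_c$city_id <- unname(city_of[deaths_c$unit_id])
  groups <- dplyr::distinct(deaths_c, .data$city_id, .data$sex)
  draws_all <- purrr::pmap_dfr(groups, function(city_id, sex) {
    d <- deaths_c[deaths_c$city_id == city_id & deaths_c$sex == sex,
                  c("unit_id", "sex", "age_lower", "year", "deaths")]
    p <- population[population$unit_id %in% unique(d$unit_id) &
                      population$sex == sex, ]
    scfg <- cf$smoothing
    scfg$seed <- (cf$seed * 7919L +
                    utf8ToInt(substr(paste0(city_id, sex), 1, 1))) %%
      .Machine$integer.max
    fit <- withCallingHandlers(
      tryCatch(fit_smoothing_model(d, p, scfg, scheme),
               error = function(e) abort(sprintf(
                 "stage smoothing failed for %s/%s: %s", city_id, sex,
                 conditionMessage(e)))),
      warning = log_warning)
    e0_draws(fit, at_ages = c(0, 40, 60),
             fit_ages = cf$gompertz_fit_ages,
             extend_to = cf$extend_to, a_first = cf$a_first)
  })

  life_expectancy <- life_expectancy_summary(draws_all)
  life_expectancy <- dplyr::left_join(
    life_expectancy, units[, c("unit_id", "city_id", "mean_population")],
    by = "unit_id"
  )

  ## stage: inequality + ICC
  outcome_col <- paste0("e", cf$outcome_age)
  value_col <- paste0(outcome_col, "_median")
  w_col <- if (cf$weighted_quantiles) "mean_population" else NULL
  ineq_data <- life_expectancy
  if (is.null(w_col)) {
    ineq_data$.unit_weight <- 1
    w_col <- ".unit_weight"
  }
  inequality <- inequality_summary(ineq_data, value = value_col, weight = w_col)
  icc <- ineq_data |>
    dplyr::group_by(.data$sex) |>
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$city_id)) < 2) {
        return(tibble::tibble(icc = NA_real_, var_between = NA_real_,
                              var_within = NA_real_, singular = NA))
      }
      icc_life_expectancy(df, value = value_col)
    }) |>
    dplyr::ungroup()

  ## stage: association
  association <- association_pipeline(
    draws_all, units, exposure = cf$exposure, outcome = outcome_col,
    adjust_builtup = TRUE, spatial_adjust = cf$spatial_adjust
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("lexgap")),
    r_version = R.version.string,
    seed = cf$seed,
    undercount_mode = cf$undercount_mode,
    outcome_age = cf$outcome_age,
    exposure = cf$exposure,
    spatial_adjust = cf$spatial_adjust,
    smoothing = unclass(cf$smoothing)[c("burn_in", "iterations", "n_draws",
                                        "chains")],
    n_units = nrow(units),
    n_cities = length(unique(units$city_id)),
    death_years = death_years,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warnings_log
  )

  bundle <- structure(list(
    coverage = coverage, life_expectancy = life_expectancy,
    e0_draws = draws_all, inequality = inequality, icc = icc,
    association = association, units = units, manifest = manifest
  ), class = "pipeline_bundle")

  if (!is.null(cf$outdir)) {
    if (!dir.exists(cf$outdir)) dir.create(cf$outdir, recursive = TRUE)
    readr::write_csv(coverage, file.path(cf$outdir, "coverage.csv"), progress = FALSE)
    readr::write_csv(life_expectancy,
                     file.path(cf$outdir, "life_expectancy.csv"), progress = FALSE)
    readr::write_csv(inequality, file.path(cf$outdir, "inequality.csv"), progress = FALSE)
    readr::write_csv(icc, file.path(cf$outdir, "icc.csv"), progress = FALSE)
    readr::write_csv(association, file.path(cf$outdir, "association.csv"), progress = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(cf$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      writeLines(utils::capture.output(utils::str(manifest)),
                 file.path(cf$outdir, "manifest.txt"))
    }
  }
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle> ", x$manifest$n_units, " units in ",
      x$manifest$n_cities, " city(ies); mode ", x$manifest$undercount_mode,
      "\n", sep = "")
  invisible(x)
}

fmt1 <- function(x) formatC(round(x, 1), format = "f", digits = 1)

#' Per-city summary table
#'
#' One row per city and sex with the population-weighted mean of the unit
#' median life expectancies, the weighted P90-P10 deciles rendered as
#' `"p10 to p90 (gap)"`, and the pooled SES-association coefficient with
#' its 95% CI, all at one-decimal rounding.
#'
#' @param bundle A [run_pipeline()] result.
#' @return A tibble: `city_id, sex, mean_e0, deciles, gap, association`.
#' @export
make_table2 <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  le <- bundle$life_expectancy
  value_col <- grep("^e\\d+_median$", names(le), value = TRUE)[1]
  means <- le |>
    dplyr::group_by(.data$city_id, .data$sex) |>
    dplyr::summarise(
      mean_e0 = sum(.data[[value_col]] * .data$mean_population) /
        sum(.data$mean_population),
      n_units = dplyr::n(), .groups = "drop"
    )
  empty <- means$n_units == 0 | is.na(means$mean_e0)
  if (any(empty)) {
    warn(sprintf("make_table2: omitting empty city row(s): %s",
                 paste(means$city_id[empty], collapse = ", ")))
    means <- means[!empty, ]
  }
  out <- means |>
    dplyr::left_join(bundle$inequality, by = c("city_id", "sex")) |>
    dplyr::left_join(
      bundle$association[, c("city_id", "sex", "coef", "lo95", "hi95")],
      by = c("city_id", "sex")
    ) |>
    dplyr::mutate(
      mean_e0 = round(.data$mean_e0, 1),
      deciles = render_decile_cell(.data$p10, .data$p90),
      gap = round(.data$gap, 1),
      association = sprintf("%s (%s to %s)", fmt1(.data$coef),
                            fmt1(.data$lo95), fmt1(.data$hi95))
    )
  out[, c("city_id", "sex", "mean_e0", "deciles", "gap", "association")]
}

#' Render a decile pair as a report cell
#'
#' Formats a P10/P90 pair as `"p10 to p90 (gap)"` with one-decimal
#' rounding, e.g. `"71.3 to 86.3 (15.0)"`.
#'
#' @param p10,p90 Decile values (vectorised).
#' @return Character vector of cells.
#' @export
render_decile_cell <- function(p10, p90) {
  sprintf("%s to %s (%s)", fmt1(p10), fmt1(p90), fmt1(p90 - p10))
}
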