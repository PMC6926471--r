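#' Read and validate a death-count table
#'
#' Long-format CSV with columns `unit_id, sex, age_lower, year, deaths`.
#' Age groups are encoded by their lower bound; sex is `male`/`female`.
#' Rows with unknown sex or an age group outside the scheme are dropped
#' with a warning; negative counts are an error. Counts may be non-integer
#' (they are after 1/coverage correction).
#'
#' @param path Path to a CSV file.
#' @param scheme An [age_scheme()].
#' @return A tibble with the five columns above, sorted by stratum.
#' @export
read_death_table <- function(path, scheme = age_scheme()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_death_table(df, scheme)
}

#' Validate an in-memory death table
#' @inheritParams read_death_table
#' @param deaths A data frame shaped like the CSV contract of
#'   [read_death_table()].
#' @return A validated tibble.
#' @export
validate_death_table <- function(deaths, scheme = age_scheme()) {
  validate_strata(deaths, scheme, "deaths", "death table")
}

#' Read and validate a population table
#'
#' Long-format CSV with columns `unit_id, sex, age_lower, year, population`.
#' One extra trailing year beyond the death window is permitted (the
#' death-distribution methods need populations at two time points).
#'
#' @inheritParams read_death_table
#' @return A tibble with the five columns, sorted by stratum.
#' @export
read_population_table <- function(path, scheme = age_scheme()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_population_table(df, scheme)
}

#' Validate an in-memory population table
#' @inheritParams read_death_table
#' @param population A data frame shaped like the CSV contract of
#'   [read_population_table()].
#' @param deaths Optional validated death table; if supplied, any stratum
#'   with deaths but zero population is an error.
#' @return A validated tibble.
#' @export
validate_population_table <- function(population, scheme = age_scheme(),
                                      deaths = NULL) {
  pop <- validate_strata(population, scheme, "population", "population table")
  if (any(pop$population < 0)) abort("population table: negative population")
  if (!is.null(deaths)) {
    joined <- dplyr::inner_join(
      deaths, pop,
      by = c("unit_id", "sex", "age_lower", "year")
    )
    bad <- joined$deaths > 0 & joined$population <= 0
    if (any(bad)) {
      abort(sprintf(
        "population is 0 where deaths > 0 in %d stratum(s), e.g. unit %s",
        sum(bad), joined$unit_id[which(bad)[1]]
      ))
    }
  }
  pop
}

#' Read and validate subcity-unit attributes
#'
#' CSV with columns `unit_id, city_id, education, water, overcrowding,
#' builtup, lon, lat`. The four socioeconomic/urbanisation variables are
#' proportions in \[0, 1\]: share of adults (25+) with completed secondary
#' education, of households with piped water, of households overcrowded,
#' and of the unit's area that is built-up.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble, one row per unit.
#' @export
read_unit_attributes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_unit_attributes(df)
}

#' Validate in-memory unit attributes
#' @param units A data frame shaped like the CSV contract of
#'   [read_unit_attributes()].
#' @return A validated tibble.
#' @export
validate_unit_attributes <- function(units) {
  required <- c("unit_id", "city_id", "education", "water", "overcrowding",
                "builtup", "lon", "lat")
  missing <- setdiff(required, names(units))
  if (length(missing)) {
    abort(sprintf("unit attributes missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  units <- tibble::as_tibble(units)
  units$unit_id <- as.character(units$unit_id)
  units$city_id <- as.character(units$city_id)
  for (col in c("education", "water", "overcrowding", "builtup")) {
    v <- as.numeric(units[[col]])
    if (any(is.na(v) | v < 0 | v > 1)) {
      abort(sprintf("unit attributes: %s must be a proportion in [0, 1]", col))
    }
    units[[col]] <- v
  }
  if (anyDuplicated(units$unit_id)) {
    abort("unit attributes: duplicated unit_id (each unit belongs to one city)")
  }
  units[order(units$unit_id), union(required, names(units))]
}

#' Write a pipeline table as CSV
#'
#' Plain UTF-8 comma-separated output with a `.` decimal mark, mirroring
#' the input conventions so that writer and reader are inverse.
#'
#' @param x A tibble (death table, population table, unit attributes, or
#'   any downstream result table).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_lexgap_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}
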