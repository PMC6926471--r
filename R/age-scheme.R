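#' Five-year age-group scheme with an open last interval
#'
#' The analysis stratifies everything by 5-year age groups (0-4, 5-9, ...)
#' capped with an open-ended last group. Each group is encoded by its lower
#' bound in years, so the default scheme is `0, 5, ..., 75` with `75+` open.
#'
#' @param open_lower Lower bound, in years, of the open-ended last group.
#' @param width Width of the closed groups, in years.
#' @return An object of class `age_scheme`: a list with `lower` (integer
#'   lower bounds), `width`, `open_lower`, and `midpoints` (interval
#'   midpoints used for hazard evaluation; the open interval uses
#'   `open_lower + width`).
#' @examples
#' sch <- age_scheme()
#' sch$lower
#' @export
age_scheme <- function(open_lower = 75, width = 5) {
  stopifnot(open_lower > 0, width > 0, open_lower %% width == 0)
  lower <- seq(0L, as.integer(open_lower), by = as.integer(width))
  mid <- lower + width / 2
  mid[length(mid)] <- open_lower + width  # open interval convention
  structure(
    list(lower = lower, width = width, open_lower = open_lower, midpoints = mid),
    class = "age_scheme"
  )
}

#' @export
print.age_scheme <- function(x, ...) {
  cat("<age_scheme> ", length(x$lower), " groups: ",
      paste0(head(x$lower, 3), collapse = ", "), ", ..., ",
      x$open_lower, "+ (width ", x$width, ")\n", sep = "")
  invisible(x)
}

n_groups <- function(scheme) length(scheme$lower)

# Internal: check that a vector of age lower bounds belongs to the scheme.
check_age_lower <- function(age_lower, scheme, what = "age_lower") {
  bad <- !age_lower %in% scheme$lower
  if (any(bad)) {
    abort(sprintf("%d %s value(s) not in the age scheme (e.g. %s)",
                  sum(bad), what, paste0(head(unique(age_lower[bad]), 3), collapse = ", ")))
  }
  invisible(TRUE)
}

SEXES <- c("male", "female")

# Internal: shared stratum validation for death/population tables.
validate_strata <- function(df, scheme, count_col, table_name) {
  required <- c("unit_id", "sex", "age_lower", "year", count_col)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", table_name,
                  paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  df$unit_id <- as.character(df$unit_id)
  df$sex <- tolower(as.character(df$sex))
  df$age_lower <- as.numeric(df$age_lower)
  df$year <- as.integer(df$year)
  df[[count_col]] <- as.numeric(df[[count_col]])

  unknown <- !(df$sex %in% SEXES) | !(df$age_lower %in% scheme$lower) |
    is.na(df[[count_col]])
  if (any(unknown)) {
    warn(sprintf("%s: dropping %d row(s) with unknown sex, unknown age group, or missing %s",
                 table_name, sum(unknown), count_col))
    df <- df[!unknown, , drop = FALSE]
  }
  neg <- df[[count_col]] < 0
  if (any(neg)) {
    abort(sprintf("%s: negative %s in row(s) %s", table_name, count_col,
                  paste(head(which(neg), 5), collapse = ", ")))
  }
  key <- paste(df$unit_id, df$sex, df$age_lower, df$year)
  if (anyDuplicated(key)) {
    abort(sprintf("%s: duplicated (unit_id, sex, age_lower, year) strata", table_name))
  }
  df[order(df$unit_id, df$sex, df$age_lower, df$year), required]
}
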