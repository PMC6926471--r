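#' Fit a Gompertz hazard to adult age-specific rates
#'
#' Ordinary least squares of log rate on age-group midpoint over the
#' groups whose lower bounds fall in `fit_ages` (default 45-70, i.e.
#' midpoints 47.5-72.5). Under the Gompertz law `m(x) = A exp(B x)` this
#' line has intercept `log A` and slope `B`.
#'
#' @param rates Age-specific mortality rates (per person-year), ordered as
#'   `scheme$lower`.
#' @param scheme An [age_scheme()].
#' @param fit_ages Interval of group lower bounds used in the fit.
#' @return A list of class `gompertz_fit`: `A`, `B`, `r_squared`,
#'   `fit_ages`.
#' @export
fit_gompertz <- function(rates, scheme = age_scheme(), fit_ages = c(45, 70)) {
  stopifnot(length(rates) == n_groups(scheme))
  sel <- scheme$lower >= fit_ages[1] & scheme$lower <= fit_ages[2]
  if (sum(sel) < 3) abort("fit_gompertz: need at least 3 age groups in range")
  if (any(rates[sel] <= 0)) abort("fit_gompertz: non-positive rate in fit range")
  x <- scheme$lower[sel] + scheme$width / 2
  y <- log(rates[sel])
  xc <- x - mean(x)
  B <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - B * mean(x)
  fitted <- intercept + B * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    A = exp(intercept), B = B,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    fit_ages = fit_ages
  ), class = "gompertz_fit")
}

#' Extend a rate schedule beyond the open interval with a Gompertz fit
#'
#' Observed rates are kept for groups below the open age; the former open
#' group and all new 5-year groups up to `extend_to` take the Gompertz
#' prediction at their midpoints, with the new open group (`extend_to`+)
#' evaluated at `extend_to + width/2`.
#'
#' @param rates Rates on the original scheme (open at `scheme$open_lower`).
#' @param fit A [fit_gompertz()] result.
#' @param scheme The original [age_scheme()].
#' @param extend_to Lower bound of the new open group.
#' @return A list with `rate` (extended schedule) and `lower` (extended
#'   lower bounds).
#' @export
extrapolate_rates <- function(rates, fit, scheme = age_scheme(),
                              extend_to = 105) {
  stopifnot(inherits(fit, "gompertz_fit"), length(rates) == n_groups(scheme))
  w <- scheme$width
  keep <- scheme$lower < scheme$open_lower
  new_lower <- seq(scheme$open_lower, extend_to, by = w)
  mid <- new_lower + w / 2
  list(
    rate = c(rates[keep], fit$A * exp(fit$B * mid)),
    lower = c(scheme$lower[keep], new_lower)
  )
}

#' Build an abridged life table from a rate schedule
#'
#' Standard abridged life-table construction: death probabilities
#' `q = n m / (1 + (n - a) m)` from central rates `m`, with `a` the average
#' years lived in the interval by those dying in it (`n/2` except the
#' first group, see `a_first`), the open interval closed with `q = 1` and
#' `L = l/m`, and the usual `l, d, L, T, e` recursion from a radix of
#' 100 000.
#'
#' @param rates Central death rates per group, last group open.
#' @param lower Group lower bounds (years).
#' @param a_first Average years lived in the first (0-4) interval by those
#'   dying in it; deaths in this group are concentrated in infancy, so the
#'   default 1.0 sits well below the interval midpoint.
#' @param radix Starting cohort size.
#' @return A tibble of class `lexgap_lifetable` with columns
#'   `age, n, m, a, q, l, d, L, T, e`.
#' @export
build_life_table <- function(rates, lower, a_first = 1.0, radix = 1e5) {
  K <- length(rates)
  stopifnot(length(lower) == K, K >= 2, all(rates >= 0))
  if (rates[K] <= 0) abort("build_life_table: open-interval rate must be > 0")
  n <- c(diff(lower), Inf)
  a <- n / 2
  a[1] <- a_first
  q <- n * rates / (1 + (n - a) * rates)
  q <- pmin(pmax(q, 0), 1)
  q[K] <- 1
  l <- radix * cumprod(c(1, 1 - q[-K]))
  d <- l * q
  L <- n * (l - d) + a * d
  L[K] <- l[K] / rates[K]
  T_ <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T_ / l, 0)
  out <- tibble::tibble(age = lower, n = n, m = rates, a = a, q = q,
                        l = l, d = d, L = L, T = T_, e = e)
  class(out) <- c("lexgap_lifetable", class(out))
  out
}

#' Life expectancy at an exact age from a life table
#'
#' Returns `e(x) = T(x)/l(x)` at a group boundary `x` (0, 40 and 60 are
#' the ages used in the main analysis and sensitivity analyses).
#'
#' @param table A [build_life_table()] result.
#' @param age A group boundary present in the table.
#' @return Remaining life expectancy in years.
#' @export
life_expectancy_at <- function(table, age = 0) {
  i <- match(age, table$age)
  if (is.na(i)) abort(sprintf("age %s is not a group boundary of the table", age))
  table$T[i] / table$l[i]
}

# Vectorised life-expectancy-at-boundary over a draws x ages rate matrix.
# One Gompertz fit + extension + life table per row, in matrix form.
e0_matrix <- function(rate_mat, scheme, fit_ages = c(45, 70),
                      extend_to = 105, a_first = 1.0,
                      at_ages = c(0, 40, 60)) {
  w <- scheme$width
  sel <- scheme$lower >= fit_ages[1] & scheme$lower <= fit_ages[2]
  x <- scheme$lower[sel] + w / 2
  xc <- x - mean(x)
  Y <- log(rate_mat[, sel, drop = FALSE])
  B <- (Y %*% xc) / sum(xc^2)                       # per-draw slope
  intercept <- rowMeans(Y) - B[, 1] * mean(x)
  keep <- scheme$lower < scheme$open_lower
  new_lower <- seq(scheme$open_lower, extend_to, by = w)
  mid <- new_lower + w / 2
  ext <- exp(outer(B[, 1], mid) + intercept)        # predicted old-age rates
  M <- cbind(rate_mat[, keep, drop = FALSE], ext)
  lower <- c(scheme$lower[keep], new_lower)
  K <- length(lower)
  n <- c(diff(lower), Inf)
  a <- n / 2; a[1] <- a_first
  q <- sweep(M, 2, n, "*") / (1 + sweep(M, 2, n - a, "*"))
  q <- pmin(pmax(q, 0), 1)
  q[, K] <- 1
  log1mq <- log(pmax(1 - q[, -K, drop = FALSE], .Machine$double.xmin))
  l <- cbind(1, exp(t(apply(log1mq, 1, cumsum)))) * 1e5
  d <- l * q
  L <- sweep(l - d, 2, n, "*") + sweep(d, 2, a, "*")
  L[, K] <- l[, K] / M[, K]
  T_ <- t(apply(L[, K:1, drop = FALSE], 1, cumsum))[, K:1, drop = FALSE]
  out <- sapply(at_ages, function(ag) {
    i <- match(ag, lower)
    T_[, i] / l[, i]
  })
  out <- matrix(out, ncol = length(at_ages))
  colnames(out) <- paste0("e", at_ages)
  out
}

#' Life expectancy draws from posterior mortality rates
#'
#' For every posterior draw and unit, fits the adult Gompertz line,
#' extends the schedule past the open interval, builds the abridged life
#' table, and evaluates life expectancy at the requested ages.
#'
#' @param fit A `lexgap_smooth` object from [fit_smoothing_model()], or a
#'   long tibble with columns `draw, unit_id, sex, age_lower, rate`.
#' @param at_ages Exact ages at which to evaluate expectancy.
#' @param fit_ages,extend_to,a_first Passed to the life-table pipeline
#'   (see [fit_gompertz()], [extrapolate_rates()], [build_life_table()]).
#' @return A tibble: `draw, unit_id, sex, e0` (and `e40`, `e60`, ... for
#'   the other requested ages).
#' @export
e0_draws <- function(fit, at_ages = c(0, 40, 60), fit_ages = c(45, 70),
                     extend_to = 105, a_first = 1.0) {
  if (inherits(fit, "lexgap_smooth")) {
    scheme <- fit$scheme
    draws <- fit$draws  # [n_draws, U, A]
    res <- purrr::map_dfr(seq_along(fit$unit_ids), function(u) {
      e <- e0_matrix(draws[, u, , drop = TRUE], scheme, fit_ages, extend_to,
                     a_first, at_ages)
      tibble::as_tibble(e) |>
        dplyr::mutate(draw = dplyr::row_number(),
                      unit_id = fit$unit_ids[u], sex = fit$sex,
                      .before = 1)
    })
    return(res)
  }
  stopifnot(all(c("draw", "unit_id", "sex", "age_lower", "rate") %in% names(fit)))
  scheme <- age_scheme(open_lower = max(fit$age_lower))
  fit |>
    dplyr::group_by(.data$unit_id, .data$sex) |>
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(df, id_cols = "draw",
                                 names_from = "age_lower",
                                 values_from = "rate")
      m <- as.matrix(wide[, as.character(scheme$lower)])
      e <- e0_matrix(m, scheme, fit_ages, extend_to, a_first, at_ages)
      dplyr::bind_cols(tibble::tibble(draw = wide$draw), tibble::as_tibble(e))
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("draw")
}

#' Summarise life-expectancy draws per unit
#'
#' Median and central 95% interval of `e0` across draws, plus medians of
#' any other expectancy columns present.
#'
#' @param draws Output of [e0_draws()].
#' @return A tibble: `unit_id, sex, e0_median, e0_lo95, e0_hi95` and
#'   `e40_median`/`e60_median` when available.
#' @export
life_expectancy_summary <- function(draws) {
  extra <- intersect(c("e40", "e60"), names(draws))
  draws |>
    dplyr::group_by(.data$unit_id, .data$sex) |>
    dplyr::summarise(
      e0_median = median(.data$e0),
      e0_lo95 = unname(quantile(.data$e0, 0.025, type = 7)),
      e0_hi95 = unname(quantile(.data$e0, 0.975, type = 7)),
      dplyr::across(dplyr::all_of(extra), median, .names = "{.col}_median"),
      .groups = "drop"
    )
}
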