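#' Weighted quantile with cumulative-weight midpoint interpolation
#'
#' Each sorted value sits at the midpoint of its normalised weight band;
#' the quantile is linearly interpolated between adjacent midpoints and
#' clamped to the extreme values outside them. With equal weights this
#' reduces to the standard type-5 sample quantile.
#'
#' @param values Numeric values (e.g. unit life expectancies).
#' @param weights Positive weights (e.g. mean unit populations).
#' @param p Probability in (0, 1); vectorised.
#' @return The weighted quantile(s).
#' @export
weighted_quantile <- function(values, weights = rep(1, length(values)), p) {
  if (!length(values)) abort("weighted_quantile: empty input")
  stopifnot(length(values) == length(weights), all(weights > 0),
            all(is.finite(values)), all(p > 0 & p < 1))
  o <- order(values)
  x <- values[o]; w <- weights[o]
  cw <- cumsum(w)
  mid <- (cw - w / 2) / cw[length(cw)]
  vapply(p, function(pp) {
    if (pp <= mid[1]) return(x[1])
    if (pp >= mid[length(mid)]) return(x[length(x)])
    stats::approx(mid, x, xout = pp, ties = "ordered")$y
  }, numeric(1))
}

#' Population-weighted P90-P10 gap
#'
#' The difference between the ninth and first weighted deciles of
#' unit-level values within a city: an inequality measure on the original
#' scale (years of life expectancy).
#'
#' @inheritParams weighted_quantile
#' @return A tibble with `p10`, `p90`, `gap`.
#' @export
p90_p10_gap <- function(values, weights = rep(1, length(values))) {
  if (length(values) < 2) abort("p90_p10_gap: need at least 2 units")
  q <- weighted_quantile(values, weights, c(0.1, 0.9))
  tibble::tibble(p10 = q[1], p90 = q[2], gap = q[2] - q[1])
}

#' Weighted Gini coefficient
#'
#' The weighted relative mean absolute difference, halved:
#' `G = sum_ij w_i w_j |x_i - x_j| / (2 W^2 mean_w(x))`, using the
#' population (not sample-corrected) convention. Computed via the sorted
#' O(n log n) identity.
#'
#' @inheritParams weighted_quantile
#' @return Gini coefficient in \[0, 1).
#' @export
gini_coefficient <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), all(weights > 0),
            all(values >= 0))
  o <- order(values)
  x <- values[o]; w <- weights[o]
  W <- sum(w)
  mu <- sum(w * x) / W
  if (mu == 0) abort("gini_coefficient: weighted mean is zero")
  cw <- cumsum(w)
  # sum_{i != j} w_i w_j |x_i - x_j| = 2 * sum_j w_j x_j (cum_{j-1} + cum_j - W)
  num <- 2 * sum(w * x * (cw - w + cw - W))
  num / (2 * W^2 * mu)
}

#' Weighted coefficient of variation
#'
#' Weighted SD over weighted mean, population-variance convention.
#'
#' @inheritParams weighted_quantile
#' @return Dimensionless CV >= 0.
#' @export
coefficient_of_variation <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), all(weights > 0))
  W <- sum(weights)
  mu <- sum(weights * values) / W
  if (mu <= 0) abort("coefficient_of_variation: weighted mean must be > 0")
  sqrt(sum(weights * (values - mu)^2) / W) / mu
}

#' Within-city inequality summary
#'
#' Population-weighted P90-P10 gap, Gini coefficient and coefficient of
#' variation of unit-level life expectancy, per city and sex.
#'
#' @param data Tibble with one row per unit x sex, containing the value
#'   column, `city_id`, `sex` and a weight column.
#' @param value,weight Column names (strings) of the value and weight.
#' @return A tibble: `city_id, sex, p10, p90, gap, gini, cv, n_units`.
#' @export
inequality_summary <- function(data, value = "e0_median", weight = "mean_population") {
  stopifnot(all(c("city_id", "sex", value, weight) %in% names(data)))
  data |>
    dplyr::group_by(.data$city_id, .data$sex) |>
    dplyr::group_modify(function(df, key) {
      v <- df[[value]]; w <- df[[weight]]
      dplyr::bind_cols(
        p90_p10_gap(v, w),
        tibble::tibble(gini = gini_coefficient(v, w),
                       cv = coefficient_of_variation(v, w),
                       n_units = nrow(df))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("city_id", "sex", "p10", "p90", "gap", "gini", "cv",
                    "n_units")
}

#' Intraclass correlation of unit life expectancy across cities
#'
#' Fits a linear random-intercept model of subcity units nested in cities
#' (REML via `lme4::lmer`) and returns the share of total variance that is
#' between cities: `ICC = var_between / (var_between + var_within)`.
#' Stratify by sex by calling once per sex.
#'
#' @param data Tibble with one row per unit, containing the value column
#'   and `city_id`.
#' @param value Column name of the unit statistic.
#' @param weight Optional weight column name; by default the model is
#'   unweighted (variance-component ICCs under frequency weights are
#'   convention-dependent).
#' @return A tibble: `icc, var_between, var_within, singular`.
#' @export
icc_life_expectancy <- function(data, value = "e0_median", weight = NULL) {
  stopifnot(all(c("city_id", value) %in% names(data)))
  if (length(unique(data$city_id)) < 2) {
    abort("icc_life_expectancy: need >= 2 cities")
  }
  df <- data.frame(y = data[[value]], city = factor(data$city_id))
  args <- list(formula = y ~ 1 + (1 | city), data = df, REML = TRUE)
  if (!is.null(weight)) args$weights <- data[[weight]] / mean(data[[weight]])
  fit <- suppressMessages(do.call(lme4::lmer, args))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == "city"]
  vw <- vc$vcov[vc$grp == "Residual"]
  singular <- lme4::isSingular(fit)
  icc <- if (vb + vw > 0) vb / (vb + vw) else 0
  if (singular && vb == 0) icc <- 0
  tibble::tibble(icc = icc, var_between = vb, var_within = vw,
                 singular = singular)
}
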