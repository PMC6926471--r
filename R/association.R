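#' Scale an exposure by its weighted P90-P10 range
#'
#' Divides a socioeconomic exposure by its population-weighted P90-P10
#' range, so a one-unit change in the scaled exposure corresponds to the
#' gap between the ninth and first weighted deciles of the exposure — the
#' scale on which regression coefficients are reported.
#'
#' @param values Exposure values (e.g. proportion with completed secondary
#'   education).
#' @param weights Positive weights (mean unit populations).
#' @return The scaled exposure vector, with the range in attribute
#'   `"p90_p10_range"`.
#' @export
scale_exposure <- function(values, weights = rep(1, length(values))) {
  if (length(unique(values)) < 2) abort("scale_exposure: exposure is constant")
  q <- weighted_quantile(values, weights, c(0.1, 0.9))
  rng <- q[2] - q[1]
  if (rng <= 0) abort("scale_exposure: weighted P90-P10 range is zero")
  structure(values / rng, p90_p10_range = rng)
}

#' Weighted least squares for one life-expectancy draw
#'
#' Regresses unit life expectancy on the scaled exposure, adjusted for
#' built-up fraction and optionally a spatial polynomial in the unit
#' centroids (lon, lat, their squares and interaction, centred and scaled
#' to unit SD), weighted by mean population. Returns the exposure
#' coefficient and its sampling variance.
#'
#' @param outcome Per-unit outcome values (years).
#' @param exposure Scaled exposure (see [scale_exposure()]).
#' @param builtup Built-up proportion per unit, or `NULL` to omit.
#' @param weights Regression weights.
#' @param lon,lat Centroid coordinates; used only when `spatial = TRUE`.
#' @param spatial Add the quadratic spatial polynomial.
#' @param robust Use a heteroscedasticity-robust (sandwich) variance
#'   instead of the classical WLS variance.
#' @return A list with `coefficient` and `variance`.
#' @export
fit_wls <- function(outcome, exposure, builtup = NULL,
                    weights = rep(1, length(outcome)),
                    lon = NULL, lat = NULL, spatial = FALSE,
                    robust = FALSE) {
  X <- cbind(`(Intercept)` = 1, exposure = exposure)
  if (!is.null(builtup)) X <- cbind(X, builtup = builtup)
  if (spatial) {
    if (is.null(lon) || is.null(lat)) abort("fit_wls: spatial = TRUE needs lon/lat")
    zl <- as.numeric(scale(lon)); zt <- as.numeric(scale(lat))
    X <- cbind(X, lon = zl, lat = zt, lon2 = zl^2, lat2 = zt^2,
               lonlat = zl * zt)
  }
  if (nrow(X) < ncol(X) + 1) abort("fit_wls: too few units for the design")
  qrX <- qr(X * sqrt(weights))
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("fit_wls: collinear design, offending column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  fit <- lm.wfit(X, outcome, w = weights)
  r <- fit$residuals
  p <- ncol(X); n <- nrow(X)
  XtWX_inv <- chol2inv(qr.R(qrX))
  rownames(XtWX_inv) <- colnames(XtWX_inv) <- colnames(X)
  if (robust) {
    meat <- t(X) %*% (X * (weights^2 * r^2))
    V <- XtWX_inv %*% meat %*% XtWX_inv
  } else {
    sigma2 <- sum(weights * r^2) / (n - p)
    V <- sigma2 * XtWX_inv
  }
  list(coefficient = unname(fit$coefficients["exposure"]),
       variance = V["exposure", "exposure"])
}

#' Pool coefficients across draws with Rubin's rules
#'
#' Combines `m` repeated estimates (one per posterior draw of the
#' outcome) into a single coefficient with a total variance that adds the
#' between-draw spread to the mean within-draw variance:
#' `T = W + (1 + 1/m) B`, with a t-based 95% CI on Rubin's degrees of
#' freedom `(m - 1)(1 + W / ((1 + 1/m) B))^2` (normal when `B = 0`).
#'
#' @param coefficients Numeric vector of per-draw coefficients.
#' @param variances Matching per-draw sampling variances.
#' @return An object of class `lexgap_pooled` with fields `qbar`, `W`,
#'   `B`, `T`, `se`, `df`, `ci95`, `m`.
#' @export
rubin_pool <- function(coefficients, variances) {
  m <- length(coefficients)
  stopifnot(m >= 2, length(variances) == m, all(variances >= 0))
  qbar <- mean(coefficients)
  W <- mean(variances)
  B <- var(coefficients)
  T_ <- W + (1 + 1 / m) * B
  se <- sqrt(T_)
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    crit <- qt(0.975, df)
  } else {
    df <- Inf
    crit <- qnorm(0.975)
  }
  structure(list(qbar = qbar, W = W, B = B, T = T_, se = se, df = df,
                 ci95 = c(qbar - crit * se, qbar + crit * se), m = m),
            class = "lexgap_pooled")
}

#' @export
print.lexgap_pooled <- function(x, ...) {
  cat(sprintf("<lexgap_pooled> %.3f (95%% CI %.3f to %.3f), m = %d draws\n",
              x$qbar, x$ci95[1], x$ci95[2], x$m))
  invisible(x)
}

#' @rdname rubin_pool
#' @param x A `lexgap_pooled` object.
#' @param ... Unused.
#' @export
tidy.lexgap_pooled <- function(x, ...) {
  tibble::tibble(estimate = x$qbar, std.error = x$se,
                 conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' @rdname rubin_pool
#' @export
glance.lexgap_pooled <- function(x, ...) {
  tibble::tibble(within_var = x$W, between_var = x$B, total_var = x$T,
                 df = x$df, m = x$m)
}

#' SES-association analysis across posterior life-expectancy draws
#'
#' For each city and sex: scales the chosen exposure by its weighted
#' P90-P10 range within the city, fits the weighted regression of each
#' posterior life-expectancy draw on the scaled exposure (adjusted for
#' built-up fraction, optionally the spatial polynomial), and pools the
#' per-draw coefficients with Rubin's rules. The pooled coefficient is
#' the difference in life expectancy associated with a P90-P10 increase
#' in the exposure.
#'
#' @param draws Life-expectancy draws from [e0_draws()] (columns `draw,
#'   unit_id, sex` and the outcome).
#' @param units Unit attributes (with `mean_population`; see
#'   [add_mean_population()]).
#' @param exposure One of `"education"`, `"water"`, `"overcrowding"`.
#' @param outcome Outcome column: `"e0"`, `"e40"` or `"e60"`.
#' @param adjust_builtup Adjust for built-up fraction.
#' @param spatial_adjust Add the quadratic spatial polynomial.
#' @param robust Robust within-draw variances.
#' @return A tibble, one row per city x sex: `city_id, sex, exposure,
#'   outcome, coef, se, lo95, hi95, m, spatial_adjust`.
#' @export
association_pipeline <- function(draws, units,
                                 exposure = c("education", "water", "overcrowding"),
                                 outcome = "e0",
                                 adjust_builtup = TRUE,
                                 spatial_adjust = FALSE,
                                 robust = FALSE) {
  exposure <- match.arg(exposure)
  stopifnot(outcome %in% names(draws), "mean_population" %in% names(units))
  draws <- dplyr::inner_join(
    draws[, c("draw", "unit_id", "sex", outcome)],
    units[, c("unit_id", "city_id", exposure, "builtup", "lon", "lat",
              "mean_population")],
    by = "unit_id"
  )
  draws |>
    dplyr::group_by(.data$city_id, .data$sex) |>
    dplyr::group_modify(function(df, key) {
      u <- dplyr::distinct(df, .data$unit_id, .keep_all = TRUE)
      rng <- attr(scale_exposure(u[[exposure]], u$mean_population),
                  "p90_p10_range")
      per_draw <- df |>
        dplyr::group_by(.data$draw) |>
        dplyr::group_map(function(dd, k) {
          fit_wls(dd[[outcome]],
                  exposure = dd[[exposure]] / rng,
                  builtup = if (adjust_builtup) dd$builtup,
                  weights = dd$mean_population,
                  lon = dd$lon, lat = dd$lat,
                  spatial = spatial_adjust, robust = robust)
        })
      pooled <- rubin_pool(vapply(per_draw, `[[`, 0, "coefficient"),
                           vapply(per_draw, `[[`, 0, "variance"))
      tibble::tibble(exposure = exposure, outcome = outcome,
                     coef = pooled$qbar, se = pooled$se,
                     lo95 = pooled$ci95[1], hi95 = pooled$ci95[2],
                     m = pooled$m, spatial_adjust = spatial_adjust)
    }) |>
    dplyr::ungroup()
}

#' Mean population per unit over the study window
#'
#' Average total population (all ages and sexes) per unit over the years
#' of the population table, the weight used throughout the analysis.
#'
#' @param units Unit attributes tibble.
#' @param population Validated population table.
#' @param years Optional year subset (e.g. the death window).
#' @return `units` with a `mean_population` column.
#' @export
add_mean_population <- function(units, population, years = NULL) {
  if (!is.null(years)) population <- population[population$year %in% years, ]
  mp <- population |>
    dplyr::group_by(.data$unit_id, .data$year) |>
    dplyr::summarise(total = sum(.data$population), .groups = "drop_last") |>
    dplyr::summarise(mean_population = mean(.data$total), .groups = "drop")
  dplyr::left_join(units, mp, by = "unit_id")
}
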