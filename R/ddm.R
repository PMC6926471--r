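#' Generalised growth balance (GGB) completeness estimate
#'
#' Estimates death-registration completeness from two population age
#' profiles and the mean annual death profile between them. For each
#' cutoff age `a` in the fit range the method forms the balance-equation
#' residual `b(a+) - r(a+)` (entry rate minus growth rate above `a`) and
#' regresses it on the observed death rate `d(a+)`; under constant
#' completeness `c` the slope is `1/c` and the intercept measures relative
#' census-coverage change.
#'
#' @param pop_t1,pop_t2 Numeric vectors of population by age group at the
#'   two time points, ordered as `scheme$lower` (open last group).
#' @param deaths Mean annual deaths by age group over the window.
#' @param window Years between the two population time points.
#' @param fit_range Cutoff-age interval (years) used for the fit.
#' @param scheme An [age_scheme()].
#' @param method Line fit: `"tls"` (orthogonal / reduced-major-axis, the
#'   death-distribution-literature standard) or `"ols"`.
#' @return A list of class `ggb_fit`: `completeness`, `slope`,
#'   `intercept`, `failed` flag, and a `diagnostics` tibble of the fitted
#'   points (cutoff age, entry, growth, death rates).
#' @export
ggb_coverage <- function(pop_t1, pop_t2, deaths, window,
                         fit_range = c(15, 65), scheme = age_scheme(),
                         method = c("tls", "ols")) {
  method <- match.arg(method)
  K <- n_groups(scheme)
  stopifnot(length(pop_t1) == K, length(pop_t2) == K, length(deaths) == K)
  lower <- scheme$lower
  pts <- ddm_points(pop_t1, pop_t2, deaths, window, scheme)
  use <- pts$cutoff >= fit_range[1] & pts$cutoff <= fit_range[2] &
    is.finite(pts$y) & is.finite(pts$x)
  if (sum(use) < 5) abort("ggb_coverage: fewer than 5 age groups in fit range")
  x <- pts$x[use]; y <- pts$y[use]
  if (sd(x) == 0) {
    return(structure(list(completeness = NA_real_, slope = NA_real_,
                          intercept = NA_real_, failed = TRUE,
                          diagnostics = pts), class = "ggb_fit"))
  }
  slope <- if (method == "tls") {
    sd(y) / sd(x) * sign(stats::cov(x, y))
  } else {
    stats::cov(x, y) / stats::var(x)
  }
  intercept <- mean(y) - slope * mean(x)
  failed <- !is.finite(slope) || slope <= 0
  structure(list(
    completeness = if (failed) NA_real_ else 1 / slope,
    slope = slope, intercept = intercept, failed = failed,
    diagnostics = pts
  ), class = "ggb_fit")
}

# Shared GGB point construction: for each cutoff age a (group boundary
# with a closed group on each side), open-interval sums above a.
ddm_points <- function(pop_t1, pop_t2, deaths, window, scheme) {
  lower <- scheme$lower
  K <- length(lower)
  idx <- 2:K  # cutoffs 5, 10, ..., open_lower
  n1p <- rev(cumsum(rev(pop_t1)))[idx]
  n2p <- rev(cumsum(rev(pop_t2)))[idx]
  dp <- rev(cumsum(rev(deaths)))[idx]
  geo <- sqrt(n1p * n2p)
  r_plus <- log(n2p / n1p) / window
  # density of persons at exact age a: average of the adjacent groups
  w <- scheme$width
  na1 <- (pop_t1[idx - 1] + pop_t1[idx]) / (2 * w)
  na2 <- (pop_t2[idx - 1] + pop_t2[idx]) / (2 * w)
  entry <- sqrt(na1 * na2) / geo
  tibble::tibble(
    cutoff = lower[idx], entry = entry, growth = r_plus,
    death_rate = dp / geo, x = dp / geo, y = entry - r_plus
  )
}

#' Synthetic extinct generations (SEG) completeness estimate
#'
#' Reconstructs the population at each exact age from registered deaths
#' above that age under the stable-population identity (Bennett-Horiuchi):
#' each death at age `x` is projected back to age `a` with the observed
#' age-specific growth rates. Completeness at each age group is the ratio
#' of reconstructed to observed population; the returned estimate is a
#' central summary over the fit range.
#'
#' @inheritParams ggb_coverage
#' @param delta Census-coverage adjustment: observed populations at `t2`
#'   are multiplied by `exp(delta * window)` before reconstruction (use a
#'   GGB intercept-derived value for the GGB-adjusted variant; 0 = plain
#'   SEG).
#' @param summary Central summary of the per-age completeness ratios:
#'   `"mean"` (default) or `"median"`.
#' @return A list of class `seg_fit`: `completeness`, `failed`, and a
#'   `diagnostics` tibble with per-age-group ratios.
#' @export
seg_coverage <- function(pop_t1, pop_t2, deaths, window,
                         fit_range = c(15, 65), scheme = age_scheme(),
                         delta = 0, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  K <- n_groups(scheme)
  stopifnot(length(pop_t1) == K, length(pop_t2) == K, length(deaths) == K)
  if (sum(deaths) <= 0) {
    return(structure(list(completeness = NA_real_, failed = TRUE,
                          diagnostics = tibble::tibble()), class = "seg_fit"))
  }
  lower <- scheme$lower
  w <- scheme$width
  pop_t2 <- pop_t2 * exp(delta * window)
  r_g <- log(pop_t2 / pop_t1) / window          # per-group growth
  r_g[!is.finite(r_g)] <- 0
  pop_mid <- sqrt(pop_t1 * pop_t2)              # mid-period population

  # Remaining life expectancy at the open age under an assumed constant
  # hazard; iterate since the observed open-interval rate is deflated by
  # the (unknown) completeness.
  comp <- 1
  for (iter in 1:4) {
    mu_open <- deaths[K] / comp / pop_mid[K]
    if (!is.finite(mu_open) || mu_open <= 0) {
      return(structure(list(completeness = NA_real_, failed = TRUE,
                            diagnostics = tibble::tibble()), class = "seg_fit"))
    }
    e_open <- 1 / (mu_open + r_g[K])
    # N(exact a): recursion from the top (Bennett-Horiuchi)
    n_exact <- numeric(K)                       # exact ages lower[2..K]; n_exact[i] = N(lower[i])
    n_exact[K] <- deaths[K] * exp(r_g[K] * e_open) * (1 - (r_g[K] * e_open)^2 / 6)
    for (i in (K - 1):1) {
      n_exact[i] <- n_exact[i + 1] * exp(w * r_g[i]) + deaths[i] * exp(w / 2 * r_g[i])
    }
    # reconstructed group populations by trapezoid between exact ages;
    # group i covers [lower[i], lower[i+1]): uses N(lower[i]), N(lower[i+1])
    rec <- numeric(K)
    for (i in 2:(K - 1)) rec[i] <- w * (n_exact[i] + n_exact[i + 1]) / 2
    ratio <- rec[2:(K - 1)] / pop_mid[2:(K - 1)]
    cut <- lower[2:(K - 1)]
    use <- cut >= fit_range[1] & cut <= fit_range[2] & is.finite(ratio)
    if (!any(use)) {
      return(structure(list(completeness = NA_real_, failed = TRUE,
                            diagnostics = tibble::tibble()), class = "seg_fit"))
    }
    comp_new <- if (summary == "mean") mean(ratio[use]) else median(ratio[use])
    if (!is.finite(comp_new) || comp_new <= 0) {
      return(structure(list(completeness = NA_real_, failed = TRUE,
                            diagnostics = tibble::tibble()), class = "seg_fit"))
    }
    if (abs(comp_new - comp) < 1e-6) { comp <- comp_new; break }
    comp <- comp_new
  }
  diagnostics <- tibble::tibble(age_lower = cut, ratio = ratio)
  structure(list(completeness = comp, failed = FALSE,
                 diagnostics = diagnostics), class = "seg_fit")
}

#' Combine GGB and SEG completeness by harmonic mean, truncated at 1
#'
#' The two method-level estimates are combined as `2 / (1/ggb + 1/seg)`
#' (the harmonic mean, which damps the upward bias either method can show
#' under migration); any combined value above 1 is set to 1 and values
#' below 1 are left as supplied.
#'
#' @param ggb,seg Positive completeness estimates.
#' @param truncate If `FALSE`, return the raw harmonic mean (sensitivity
#'   mode).
#' @return The combined (optionally truncated) coverage.
#' @export
combine_coverage <- function(ggb, seg, truncate = TRUE) {
  if (any(!is.finite(c(ggb, seg))) || any(c(ggb, seg) <= 0)) {
    abort("combine_coverage: both estimates must be positive and finite")
  }
  hm <- 2 / (1 / ggb + 1 / seg)
  if (truncate) pmin(hm, 1) else hm
}

#' Per-unit coverage estimation from pipeline tables
#'
#' Runs [ggb_coverage()] and [seg_coverage()] for every unit x sex in a
#' death table, using the first and last available population years as the
#' two time points and mean annual deaths over the death window. Units
#' where either method fails (non-positive slope, zero deaths, ...)
#' inherit the pooled estimate of their city x sex (all units' profiles
#' summed), flagged in the output.
#'
#' @param deaths Validated death table (reported counts).
#' @param population Validated population table.
#' @param units Optional unit attributes (for city pooling on failure);
#'   without it, pooling is across all units.
#' @param scheme An [age_scheme()].
#' @param fit_range Cutoff-age interval for both methods.
#' @param ggb_method `"tls"` or `"ols"` line fit for GGB.
#' @param seg_summary `"mean"` or `"median"` SEG summary.
#' @param truncate Truncate the combined estimate at 1 (sensitivity mode:
#'   `FALSE`).
#' @return A tibble: `unit_id, sex, ggb, seg, combined, truncated,
#'   fit_lo, fit_hi, flag` (`"ok"`, `"pooled"`).
#' @export
estimate_coverage <- function(deaths, population, units = NULL,
                              scheme = age_scheme(), fit_range = c(15, 65),
                              ggb_method = "tls", seg_summary = "mean",
                              truncate = TRUE) {
  deaths <- validate_death_table(deaths, scheme)
  population <- validate_population_table(population, scheme)
  city_of <- if (!is.null(units)) {
    setNames(as.character(units$city_id), as.character(units$unit_id))
  }

  one <- function(d, p) {
    yrs <- sort(unique(p$year))
    t1 <- yrs[1]; t2 <- yrs[length(yrs)]
    window <- t2 - t1
    if (window <= 0) abort("estimate_coverage: need two population years")
    prof <- function(tbl, col, yr) {
      v <- setNames(rep(0, n_groups(scheme)), scheme$lower)
      sub <- tbl[tbl$year == yr, ]
      v[as.character(sub$age_lower)] <- sub[[col]]
      unname(v)
    }
    p1 <- prof(p, "population", t1)
    p2 <- prof(p, "population", t2)
    dyrs <- sort(unique(d$year))
    dm <- rep(0, n_groups(scheme))
    for (y in dyrs) dm <- dm + prof(d, "deaths", y)
    dm <- dm / length(dyrs)
    g <- tryCatch(ggb_coverage(p1, p2, dm, window, fit_range, scheme,
                               method = ggb_method),
                  error = function(e) list(completeness = NA_real_, failed = TRUE))
    s <- tryCatch(seg_coverage(p1, p2, dm, window, fit_range, scheme,
                               summary = seg_summary),
                  error = function(e) list(completeness = NA_real_, failed = TRUE))
    c(ggb = g$completeness, seg = s$completeness)
  }

  strata <- dplyr::distinct(deaths, .data$unit_id, .data$sex)
  res <- purrr::pmap_dfr(strata, function(unit_id, sex) {
    d <- deaths[deaths$unit_id == unit_id & deaths$sex == sex, ]
    p <- population[population$unit_id == unit_id & population$sex == sex, ]
    est <- one(d, p)
    tibble::tibble(unit_id = unit_id, sex = sex,
                   ggb = est[["ggb"]], seg = est[["seg"]])
  })

  # pooled fallback per city x sex
  failed <- !is.finite(res$ggb) | !is.finite(res$seg) | res$ggb <= 0 | res$seg <= 0
  res$flag <- ifelse(failed, "pooled", "ok")
  if (any(failed)) {
    pool_key <- function(uid) if (is.null(city_of)) "all" else city_of[[uid]]
    pools <- unique(vapply(res$unit_id[failed], pool_key, character(1)))
    for (pk in pools) {
      in_pool <- if (is.null(city_of)) rep(TRUE, nrow(res)) else
        vapply(res$unit_id, pool_key, character(1)) == pk
      for (s in unique(res$sex[failed & in_pool])) {
        uids <- res$unit_id[in_pool & res$sex == s]
        d <- deaths[deaths$unit_id %in% uids & deaths$sex == s, ] |>
          dplyr::count(.data$age_lower, .data$year, wt = .data$deaths, name = "deaths") |>
          dplyr::mutate(unit_id = "pool", sex = s)
        p <- population[population$unit_id %in% uids & population$sex == s, ] |>
          dplyr::count(.data$age_lower, .data$year, wt = .data$population, name = "population") |>
          dplyr::mutate(unit_id = "pool", sex = s)
        est <- one(d, p)
        hit <- failed & in_pool & res$sex == s
        res$ggb[hit] <- est[["ggb"]]
        res$seg[hit] <- est[["seg"]]
      }
    }
  }
  res$combined <- 2 / (1 / res$ggb + 1 / res$seg)
  res$truncated <- if (truncate) pmin(res$combined, 1) else res$combined
  res$fit_lo <- fit_range[1]
  res$fit_hi <- fit_range[2]
  res[, c("unit_id", "sex", "ggb", "seg", "combined", "truncated",
          "fit_lo", "fit_hi", "flag")]
}

#' Inflate death counts by 1/coverage
#'
#' Applies the correction factor `1/coverage` to every age-specific death
#' count of each unit x sex, producing real-valued corrected counts.
#'
#' @param deaths Validated death table.
#' @param coverage Tibble with `unit_id, sex` and a coverage column
#'   (default `truncated`) in (0, 1].
#' @param column Name of the coverage column to use (`"truncated"` or
#'   `"combined"` for the no-truncation sensitivity mode).
#' @return The death table with `deaths` divided by coverage.
#' @export
correct_deaths <- function(deaths, coverage, column = "truncated") {
  stopifnot(column %in% names(coverage))
  cov <- coverage[, c("unit_id", "sex", column)]
  names(cov)[3] <- ".coverage"
  out <- dplyr::left_join(deaths, cov, by = c("unit_id", "sex"))
  miss <- is.na(out$.coverage)
  if (any(miss)) {
    abort(sprintf("correct_deaths: no coverage for unit(s) %s",
                  paste(unique(out$unit_id[miss]), collapse = ", ")))
  }
  if (any(out$.coverage <= 0)) abort("correct_deaths: coverage must be > 0")
  out$deaths <- out$deaths / out$.coverage
  out$.coverage <- NULL
  out
}
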