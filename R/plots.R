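#' Plot smoothed age-specific mortality rates
#'
#' Posterior median rate by age for every unit (thin lines) over the
#' crude city schedule (points), log scale — the usual check that the
#' hierarchical model shrinks noisy unit schedules toward a plausible
#' age pattern.
#'
#' @param object A `lexgap_smooth` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lexgap_smooth <- function(object, ...) {
  s <- posterior_summary(object)
  crude <- tibble::tibble(
    age_lower = object$scheme$lower,
    rate = colSums(object$D) / colSums(object$PY)
  )
  ggplot2::ggplot(s, ggplot2::aes(x = .data$age_lower, y = .data$rate_median,
                                  group = .data$unit_id)) +
    ggplot2::geom_line(alpha = 0.35, colour = "steelblue") +
    ggplot2::geom_point(data = crude,
                        ggplot2::aes(y = .data$rate, group = NULL),
                        colour = "black", size = 1.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age (years)", y = "mortality rate (per person-year)",
                  title = sprintf("Smoothed age-specific rates (%s)", object$sex)) +
    ggplot2::theme_minimal()
}

#' Plot within-city life-expectancy inequality
#'
#' P10-P90 range of unit life expectancy per city and sex, with the gap
#' printed next to each segment.
#'
#' @param inequality An [inequality_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_inequality <- function(inequality) {
  ggplot2::ggplot(inequality,
                  ggplot2::aes(y = .data$city_id, colour = .data$sex)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$p10, xend = .data$p90,
                                       yend = .data$city_id),
                          linewidth = 1.2,
                          position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_text(ggplot2::aes(x = .data$p90,
                                    label = sprintf("%.1f", .data$gap)),
                       hjust = -0.3, size = 3, show.legend = FALSE,
                       position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "life expectancy at birth (years), P10 to P90",
                  y = NULL, colour = NULL,
                  title = "Within-city P90-P10 gaps") +
    ggplot2::theme_minimal()
}

#' Plot life expectancy against socioeconomic status
#'
#' Unit median life expectancy versus the exposure, point size
#' proportional to mean population, with a population-weighted linear
#' fit per city.
#'
#' @param life_expectancy The `life_expectancy` element of a pipeline
#'   bundle (needs `city_id`, `mean_population`).
#' @param units Unit attributes with the exposure column.
#' @param exposure Exposure column name.
#' @return A ggplot object.
#' @export
plot_e0_by_ses <- function(life_expectancy, units, exposure = "education") {
  df <- dplyr::left_join(life_expectancy,
                         units[, c("unit_id", exposure)], by = "unit_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[exposure]],
                                   y = .data$e0_median)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$mean_population),
                        alpha = 0.6, colour = "steelblue") +
    ggplot2::geom_smooth(ggplot2::aes(weight = .data$mean_population),
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.6) +
    ggplot2::facet_grid(sex ~ city_id) +
    ggplot2::scale_size_area(max_size = 5, guide = "none") +
    ggplot2::labs(x = exposure, y = "life expectancy at birth (years)") +
    ggplot2::theme_minimal()
}
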