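Package: lexgap
Title: Small-Area Life Expectancy, Inequality Metrics, and Socioeconomic
    Gradients for Subcity Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating life expectancy at birth for
    subcity units and summarising its within-city inequality. Starts from
    death counts and population series by unit, sex, 5-year age group and
    year; estimates death-registration completeness with the generalised
    growth balance and synthetic extinct generations methods and inflates
    deaths by 1/coverage; smooths age-specific mortality rates with a
    Bayesian hierarchical Poisson model with AR(1) age random effects;
    builds abridged life tables with Gompertz old-age extrapolation;
    summarises inequality with population-weighted P90-P10 gaps, Gini
    coefficients, coefficients of variation and intraclass correlations;
    and regresses life expectancy on area socioeconomic status across
    posterior draws, pooling coefficients with Rubin's rules. Includes a
    synthetic multi-city data generator so the whole pipeline is testable
    without restricted vital-registration microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
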