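---
title: "Methods: small-area life expectancy, inequality and SES gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area life expectancy, inequality and SES gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexgap)
```

## The problem

Within large cities, life expectancy at birth can differ by a decade or
more between administrative subdivisions ("subcity units": comunas,
delegaciones, corregimientos and the like). Quantifying those gaps from
vital-registration data raises four methodological problems that `lexgap`
addresses in sequence:

1. **Death-registration undercounting.** Registered deaths undercount true
   deaths, and the undercount is typically worse in poorer units, which
   would bias socioeconomic gradients toward zero (or reverse them).
2. **Small-unit noise.** Many units are small enough that crude
   age-specific death rates fluctuate wildly.
3. **Truncated age detail.** Population series are often only available up
   to an open 75+ group, while life expectancy depends on old-age
   mortality.
4. **Uncertainty propagation.** Unit life expectancy is an estimate;
   regressions of life expectancy on unit characteristics must carry that
   uncertainty into their confidence intervals.

## Pipeline and models

### Undercount correction (death-distribution methods)

Completeness of death registration is estimated per unit and sex with two
classical death-distribution methods operating on two population age
profiles (the first and last year of the window stand in for two
censuses) and mean annual deaths between them:

- **GGB (generalised growth balance):** for each cutoff age $a$, the
  stable-population balance $b(a+) - r(a+) = \frac{1}{c}\,d(a+)$ relates
  the entry rate into the open age segment, its growth rate and its
  registered death rate; a straight-line fit of $b - r$ on $d$ over
  cutoff ages 15-65 estimates completeness $c = 1/\text{slope}$ and
  relative census-coverage change (the intercept). The line is fitted by
  orthogonal (reduced-major-axis) regression, the standard in the
  death-distribution literature, with OLS available by argument.
- **SEG (synthetic extinct generations):** the population at each exact
  age is reconstructed from registered deaths above that age
  (Bennett-Horiuchi projection with age-specific growth rates, the open
  interval closed by an assumed constant hazard whose level is iterated
  against the completeness estimate); completeness is the mean of
  reconstructed/observed ratios over age groups 15-65 (median by
  argument).

The two estimates are combined by their **harmonic mean** — which damps
the upward bias either method can show under in-migration — and the
combined value is truncated at 1. Deaths are then inflated by
$1/\text{coverage}$, giving real-valued corrected counts. Whether
truncation should be applied per method or only to the combination is
ambiguous; `lexgap` truncates the combination only and keeps the raw
method-level estimates in the diagnostics, which preserves information
and makes the no-truncation sensitivity mode exact. Units where a method
fails (non-positive slope, zero deaths) inherit their city x sex pooled
estimate, flagged in the output. DDM is run per unit x sex; pooling the
sexes is possible upstream by summing tables but is not the default.

Sensitivity modes: `drop_below_0.9` keeps only units with truncated
coverage >= 0.9 and applies no correction; `no_truncation` corrects with
the raw harmonic mean even when it exceeds 1.

### Bayesian rate smoothing

Per city and sex, with $D_{ua}$ corrected deaths and $PY_{ua}$
person-years (both summed over the window) for unit $u$ and 5-year age
group $a$:

$$D_{ua} \sim \text{Poisson}(PY_{ua}\, e^{\alpha_a + \theta_{ua}}),$$

where $\alpha_a$ is the city-level log-rate age curve and
$\theta_{u\cdot}$ follows a mean-zero *stationary* AR(1) across the
ordered age groups: $\theta_{u1} \sim N(0, \sigma^2/(1-\rho^2))$,
$\theta_{ua} = \rho\,\theta_{u,a-1} + N(0,\sigma^2)$. The AR(1) captures
the empirical fact that a unit's excess mortality is correlated across
neighbouring age groups; as $\rho \to 0$ the deviations become
independent, and the model never forces unit curves to be parallel to the
city curve. A stationary AR(1) (not a random walk) is the natural reading
of a "first-order autoregressive" structure, and keeps the prior variance
bounded across age.

Priors are weakly informative and proper: $\alpha_a \sim N(0, 10^2)$,
$\sigma \sim \text{Half-Normal}(1)$, $\rho \sim U(-1, 1)$. Corrected
counts are non-integer; the Poisson log-likelihood only needs
$D \log\lambda - \lambda$ (the $\Gamma$-function term is constant in the
parameters), so real-valued counts are consumed directly; stochastic
rounding is available by argument.

Sampling is an adaptive Metropolis-within-Gibbs scheme written for this
model: elementwise random-walk updates for $\alpha$ (columns are
conditionally independent), checkerboard (odd/even age column) updates
for $\theta$ so that each conditional only involves fixed neighbours,
likelihood-invariant *recentering* moves $(\alpha_a, \theta_{\cdot a})
\mapsto (\alpha_a + c, \theta_{\cdot a} - c)$ accepted on the prior ratio
(these are what make the weakly identified $\alpha/\theta$ ridge mix),
and scalar updates for $\mathrm{atanh}\,\rho$ and $\log\sigma$. Proposal
scales adapt toward 44% acceptance during burn-in only, so the
post-burn-in chain is a valid fixed-kernel Markov chain. The default
schedule is 5000 burn-in and 20 000 sampling iterations with 2000
retained draws, evenly thinned across 2 chains; split-chain $\widehat R$
and autocovariance-based effective sample sizes are reported for
$\alpha$, $\rho$, $\sigma$, and $\widehat R > 1.05$ raises a warning
rather than failing silently.

### Life tables with Gompertz extension

For each posterior draw and unit, the adult log-rates (groups 45-49
through 70-74, midpoints 47.5-72.5) are fitted by OLS to the Gompertz law
$m(x) = A e^{Bx}$; observed rates are kept below age 75 and the schedule
is extended with Gompertz predictions in 5-year groups to an open 105+
group (evaluated at midpoint 107.5). Extending to 105+ rather than
leaving 85+ open costs nothing and removes a visible open-interval
artefact from the expectancies. Abridged life tables then use
$q = n m / (1 + (n-a) m)$, $a = n/2$ except the first group, the open
interval closed with $q = 1$, $L = l/m$. Because the scheme's first group
is 0-4 (ages 0 and 1-4 are not split), the separation factor for that
group defaults to $a_0 = 1.0$ — deaths in the 0-4 group are dominated by
infant deaths early in the interval — and is configurable. Life
expectancy is read off at 0 (main analysis) and 40/60 (sensitivity
outcomes less exposed to infant-mortality bias and migration). The
package's microsimulation tests show the abridged construction agrees
with exact piecewise-exponential lifetimes to well under 0.1 years.

Each unit's reported life expectancy is the **median** over the retained
posterior draws, with a central 95% interval.

### Inequality metrics

Within each city and sex, unit-level life expectancies are summarised
with population-weighted metrics (weights are the units' mean population
over the window):

- **P90-P10 gap**, on the years scale. Weighted quantiles use
  cumulative-weight midpoint interpolation: sorted values sit at the
  midpoints of their weight bands and the quantile is linearly
  interpolated between them. This rule is continuous in the weights and
  collapses to the standard type-5 sample quantile at equal weights.
- **Gini coefficient**: the weighted relative mean absolute difference,
  halved, in the population (not sample-corrected) convention — subcity
  units are the full population of units, not a sample.
- **Coefficient of variation**: weighted SD over weighted mean.

Between/within-city variance is decomposed with a random-intercept model
of units nested in cities (REML, `lme4`), reporting the intraclass
correlation $\sigma^2_b / (\sigma^2_b + \sigma^2_w)$ per sex. The mixed
model is unweighted by default (variance-component estimation under
frequency weights is convention-dependent); a weight argument exists.

### SES association with Rubin pooling

Per city and sex, each posterior draw's unit life expectancies are
regressed (WLS, population weights) on the unit's socioeconomic exposure
— education by default, piped water or overcrowding as sensitivity
proxies — scaled by the exposure's weighted P90-P10 range *within that
city*, adjusted for built-up fraction, and optionally for a quadratic
polynomial in the centred/scaled centroid coordinates (lon, lat, squares,
interaction) as a spatial-confounding check. The coefficient therefore
reads "years of life expectancy per P90-P10 difference in SES". The
2000 per-draw coefficients $\hat\beta^{(j)}$ with classical WLS variances
$v^{(j)}$ are pooled by Rubin's rules:

$$\bar Q = \tfrac1m\sum \hat\beta^{(j)},\quad
W = \tfrac1m\sum v^{(j)},\quad
B = \mathrm{Var}(\hat\beta^{(j)}),\quad
T = W + (1 + \tfrac1m)B,$$

with a $t$ interval on $\nu = (m-1)(1 + W/((1+\tfrac1m)B))^2$ degrees of
freedom ($B = 0$ falls back to the normal quantile). At $m = 2000$ the
$t$ and normal intervals coincide numerically; the $t$ form stays honest
in small-$m$ tests. Classical (not sandwich) within-draw variances are
the default, matching the weighted `lm` convention; a robust flag exists.

## The synthetic-data generator

Because the study's vital-registration microdata are restricted, the
package ships a generator that emulates the statistical structure the
analysis assumes, so every stage is testable end-to-end:

- unit education drawn from a Beta(3.5, 6) (mean ~0.37, matching the
  scale of completed-secondary-education proportions in large Latin
  American cities);
- log hazard = Gompertz-Makeham baseline ($A = 3\times10^{-5}$,
  $B = 0.095$, $C = 5\times10^{-4}$, giving baseline life expectancies of
  about 77.5 years for women and 74 for men with the default male excess
  of 0.3 on the log hazard) + `ses_beta` x centred education + stationary
  AR(1) deviations over age groups ($\rho = 0.8$, $\sigma = 0.15$);
- unit populations lognormal around 50 000 with each unit x sex given the
  stable age structure of *its own* hazard under the growth rate (1%/yr),
  so deaths and population satisfy the demographic balance that the
  death-distribution methods assume;
- true deaths Poisson(rate x population), reported deaths binomially
  thinned at a unit coverage whose logit is linear in centred education
  (base 0.9, slope 2) — the SES-linked undercounting that motivates the
  correction stage;
- a truth record with each unit's true rate schedule, true coverage and
  true life expectancy. The true $e_0$ is defined as the same abridged
  life-table functional (Gompertz extension included) applied to the true
  rate schedule, i.e. the estimand is a functional of the true rates, so
  recovery tests measure estimation error rather than discretisation
  conventions.

A separate deterministic stationary-population fixture (expected counts,
no sampling noise) supports exact-recovery tests of GGB/SEG: thinning its
deaths at a known rate must return that rate.

What the generator does **not** emulate: migration, cohort effects,
within-window rate trends, heaping and age misstatement, spatially
correlated mortality, or sex-specific age patterns beyond a proportional
shift. Passing tests demonstrate internal correctness of the estimators
under the model's own assumptions — not robustness to those realities.

## Numerical and design choices

- Age-group midpoints for hazards sit at lower bound + 2.5 years; the
  open interval is evaluated at its lower bound + 5.
- Coverage estimation needs >= 5 cutoff ages inside the fit range; the
  default range 15-65 avoids child-mortality and open-interval
  distortions.
- The GGB line fit is reduced-major-axis; the slope sign is checked and
  non-positive slopes are treated as estimation failures with the pooled
  fallback rather than silently producing negative completeness.
- In the life table $q$ is clamped to $[0, 1]$; a zero open-interval rate
  is an error (the expectancy would be undefined).
- Exchangeability: the sampler's state is keyed by unit order; permuting
  unit labels permutes outputs identically under the same seed.
- Every simulation entry point takes an explicit integer seed and uses
  one shared random stream, so all fixtures and pipeline runs are
  bit-reproducible.

The replication suite runs the heavy recovery experiments at reduced
sizes chosen to keep a full check affordable on a laptop: the
hyperparameter-recovery study uses 20 units x 16 age groups with 2 chains
of 2000 post-burn-in iterations over 20 replicates, and the end-to-end
SES-gradient study uses two cities of 12 units (one sex) with 300
retained draws per replicate. The end-to-end recovery experiment sets
complete registration (coverage 1, no SES-coverage slope) so that it
isolates estimation of the SES gradient; the undercount stage still runs
and must return ~1. Registration-error propagation is exercised
separately by the coverage-recovery tests.

## Interfaces

All user-facing functions take data frames first and return tibbles, so
stages chain with the pipe; `run_pipeline()` composes them and writes the
five report tables (`coverage.csv`, `life_expectancy.csv`,
`inequality.csv`, `icc.csv`, `association.csv`) plus a JSON manifest.
The package deliberately exposes the pipeline as R functions rather than
a shell entry point: its users script analyses in R, and each spec'd
subcommand corresponds to one exported function (`simulate_cities()`,
`estimate_coverage()`, `correct_deaths()`, `fit_smoothing_model()`,
`e0_draws()`, `inequality_summary()`, `association_pipeline()`,
`run_pipeline()`).

## Known limitations

- The DDM implementations assume negligible migration; in high-migration
  cities both completeness estimates are biased (the harmonic mean only
  damps this) and the resulting corrections inherit that bias.
- The smoothing model has no unit-level intercept beyond the AR(1)
  deviations and no covariates; strong SES gradients are partially
  absorbed by $\theta$, and shrinkage attenuates extreme units.
- The Gompertz extension assumes log-linear adult mortality continues
  beyond 75; late-life deceleration would make old-age mortality
  overstated and $e_0$ slightly understated.
- ICC from a two-level Gaussian model treats unit medians as error-free
  observations; posterior uncertainty in the medians is not propagated
  into the variance decomposition (it is propagated into the SES
  regressions).
```
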