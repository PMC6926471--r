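#' Settings for the Bayesian mortality-smoothing model
#'
#' Defaults follow the analysis protocol: a burn-in of 5000 iterations,
#' 20 000 sampling iterations, and 2000 retained rate draws per stratum,
#' evenly thinned from the post-burn-in iterations across chains.
#'
#' @param burn_in Burn-in (adaptation) iterations per chain.
#' @param iterations Post-burn-in iterations per chain.
#' @param n_draws Retained posterior draws (<= iterations x chains).
#' @param chains Number of independent chains.
#' @param seed Integer seed.
#' @param prior_alpha_sd Prior SD of the age intercepts `alpha_a`
#'   (Normal(0, sd^2)).
#' @param prior_sigma_scale Scale of the Half-Normal prior on the AR(1)
#'   innovation SD.
#' @param rounding How non-integer (coverage-corrected) death counts enter
#'   the Poisson likelihood: `"gamma"` evaluates the likelihood with the
#'   gamma-function generalisation (default), `"stochastic"` rounds counts
#'   up with probability equal to their fractional part before fitting.
#' @return A list of class `smoothing_config`.
#' @export
smoothing_config <- function(burn_in = 5000, iterations = 20000,
                             n_draws = 2000, chains = 2, seed = 1L,
                             prior_alpha_sd = 10, prior_sigma_scale = 1,
                             rounding = c("gamma", "stochastic")) {
  rounding <- match.arg(rounding)
  stopifnot(burn_in >= 0, iterations >= 1, chains >= 1,
            n_draws >= 1, n_draws <= iterations * chains)
  structure(as.list(environment()), class = "smoothing_config")
}

# log AR(1) prior of one theta matrix (U x A), stationary.
ar1_logprior <- function(theta, rho, sigma) {
  U <- nrow(theta); A <- ncol(theta)
  s1sq <- sigma^2 / (1 - rho^2)
  lp <- sum(dnorm(theta[, 1], 0, sqrt(s1sq), log = TRUE))
  if (A > 1) {
    resid <- theta[, -1, drop = FALSE] - rho * theta[, -A, drop = FALSE]
    lp <- lp + sum(dnorm(resid, 0, sigma, log = TRUE))
  }
  lp
}

#' Fit the Bayesian Poisson smoothing model for one city and sex
#'
#' Smooths age-specific mortality rates across the subcity units of one
#' city (one sex) with the hierarchical model
#' \deqn{D_{ua} \sim Poisson(PY_{ua} e^{\alpha_a + \theta_{ua}}),}
#' where \eqn{\alpha_a} is a city-level age curve and \eqn{\theta_{u\cdot}}
#' is a mean-zero stationary AR(1) sequence over the ordered age groups
#' (parameters \eqn{\rho, \sigma}), shared across units. Deaths and
#' person-years are summed over the year window before fitting. Corrected
#' counts may be non-integer; the likelihood is evaluated with the
#' gamma-function generalisation of the Poisson.
#'
#' Sampling uses an adaptive Metropolis-within-Gibbs scheme (elementwise
#' random-walk updates for `alpha` and checkerboard updates for `theta`,
#' scalar updates for transformed `rho` and `sigma`), with proposal scales
#' adapted only during burn-in. Split-chain potential-scale-reduction
#' (Rhat) and effective sample sizes are computed for `alpha`, `rho` and
#' `sigma`; Rhat above 1.05 on any monitored quantity triggers a warning.
#'
#' @param deaths Validated death table restricted to one sex (and one
#'   city's units); corrected counts allowed.
#' @param population Matching population table; person-years per stratum
#'   are the sum of the population over the death-window years.
#' @param config A [smoothing_config()].
#' @param scheme An [age_scheme()].
#' @return An object of class `lexgap_smooth`: list with `draws` (array
#'   `[n_draws, units, age groups]` of rates), `unit_ids`, `sex`,
#'   `scheme`, `diagnostics` (tibble of Rhat/ESS), `hyper` (tibble of
#'   retained `rho`, `sigma` draws), and `config`.
#' @export
fit_smoothing_model <- function(deaths, population,
                                config = smoothing_config(),
                                scheme = age_scheme()) {
  stopifnot(inherits(config, "smoothing_config"))
  deaths <- validate_death_table(deaths, scheme)
  sex <- unique(deaths$sex)
  if (length(sex) != 1) abort("fit_smoothing_model: supply exactly one sex")
  unit_ids <- sort(unique(deaths$unit_id))
  population <- validate_population_table(population, scheme)
  population <- population[population$sex == sex &
                             population$year %in% unique(deaths$year) &
                             population$unit_id %in% unit_ids, ]
  U <- length(unit_ids); A <- n_groups(scheme)
  if (U < 2) abort("fit_smoothing_model: need >= 2 units")

  to_mat <- function(tbl, col) {
    m <- matrix(0, U, A, dimnames = list(unit_ids, scheme$lower))
    agg <- dplyr::count(tbl, .data$unit_id, .data$age_lower,
                        wt = .data[[col]], name = "v")
    m[cbind(match(agg$unit_id, unit_ids),
            match(agg$age_lower, scheme$lower))] <- agg$v
    m
  }
  D <- to_mat(deaths, "deaths")
  PY <- to_mat(population, "population")
  if (any(PY <= 0)) abort("fit_smoothing_model: person-years must be > 0 in every stratum")

  set.seed(config$seed)
  if (config$rounding == "stochastic") {
    fl <- floor(D)
    D <- fl + (matrix(runif(U * A), U, A) < (D - fl))
  }
  logPY <- log(PY)

  n_per_chain <- ceiling(config$n_draws / config$chains)
  keep_idx <- unique(round(seq(1, config$iterations, length.out = n_per_chain)))

  chains <- lapply(seq_len(config$chains), function(ch) {
    run_smoothing_chain(D, PY, logPY, config, chain_id = ch,
                        keep_idx = keep_idx)
  })

  # retained draws: interleave chains, trim to n_draws
  rate_list <- lapply(chains, `[[`, "rates")
  rates <- do.call(abind3, rate_list)
  hyper <- dplyr::bind_rows(lapply(seq_along(chains), function(ch) {
    tibble::tibble(chain = ch,
                   rho = chains[[ch]]$rho_keep,
                   sigma = chains[[ch]]$sigma_keep)
  }))
  take <- seq_len(min(config$n_draws, dim(rates)[1]))
  rates <- rates[take, , , drop = FALSE]
  hyper <- hyper[take, ]
  dimnames(rates) <- list(NULL, unit_ids, scheme$lower)

  diagnostics <- smoothing_diagnostics(chains, A)

  bad <- diagnostics$rhat > 1.05
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf("smoothing model: Rhat > 1.05 for %s — inspect diagnostics",
                 paste(diagnostics$param[which(bad)], collapse = ", ")))
  }

  structure(list(
    draws = rates, unit_ids = unit_ids, sex = sex, scheme = scheme,
    diagnostics = diagnostics, hyper = hyper,
    D = D, PY = PY, config = config
  ), class = "lexgap_smooth")
}

# bind 3-d arrays along dim 1
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1], 0)), d[2], d[3]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

# One adaptive Metropolis-within-Gibbs chain. Elementwise random-walk
# updates for alpha and (checkerboard) theta, likelihood-invariant
# recentering moves along the alpha_a/theta_.a ridge, and scalar updates
# for transformed rho and sigma. Proposal scales adapt during burn-in only.
run_smoothing_chain <- function(D, PY, logPY, config, chain_id, keep_idx) {
  U <- nrow(D); A <- ncol(D)
  crude <- (colSums(D) + 0.5) / colSums(PY)
  alpha <- log(crude) + rnorm(A, 0, 0.1)
  theta <- matrix(rnorm(U * A, 0, 0.05), U, A)
  rho_t <- atanh(runif(1, -0.2, 0.2))   # atanh(rho)
  lsig <- log(runif(1, 0.3, 0.7))       # log(sigma)

  # adaptive proposal log-scales
  ls_alpha <- rep(log(0.1), A)
  ls_theta <- matrix(log(0.2), U, A)
  ls_shift <- rep(log(0.2), A)
  ls_rho <- log(0.3); ls_sig <- log(0.3)
  target <- 0.44

  lam <- PY * exp(sweep(theta, 2, alpha, "+"))

  n_iter <- config$burn_in + config$iterations
  parity <- list(seq(1, A, by = 2), seq(2, A, by = 2))

  n_keep <- length(keep_idx)
  rates <- array(NA_real_, c(n_keep, U, A))
  rho_keep <- numeric(n_keep); sigma_keep <- numeric(n_keep)
  alpha_trace <- matrix(NA_real_, config$iterations, A)
  rho_trace <- numeric(config$iterations); sig_trace <- numeric(config$iterations)
  k <- 0L

  pa_sd <- config$prior_alpha_sd
  ps <- config$prior_sigma_scale

  for (it in seq_len(n_iter)) {
    adapting <- it <= config$burn_in
    gam <- if (adapting) min(0.5, 5 / sqrt(it)) else 0
    rho <- tanh(rho_t); sigma <- exp(lsig)
    s1sq <- sigma^2 / (1 - rho^2)

    ## alpha update (columns independent given theta)
    eps <- rnorm(A) * exp(ls_alpha)
    # D*eps - lam*(e^eps - 1), columnwise
    dll <- colSums(sweep(D, 2, eps, "*") - sweep(lam, 2, expm1(eps), "*"))
    dpr <- (alpha^2 - (alpha + eps)^2) / (2 * pa_sd^2)
    lr <- dll + dpr
    acc <- log(runif(A)) < lr
    if (any(acc)) {
      alpha[acc] <- alpha[acc] + eps[acc]
      lam[, acc] <- sweep(lam[, acc, drop = FALSE], 2, exp(eps[acc]), "*")
    }
    if (adapting) ls_alpha <- ls_alpha + gam * (pmin(1, exp(lr)) - target)

    ## theta update, checkerboard over age columns
    for (B in parity) {
      nb <- length(B)
      first <- B == 1
      has_next <- B < A
      cur <- theta[, B, drop = FALSE]
      eps <- matrix(rnorm(U * nb), U) * exp(ls_theta[, B, drop = FALSE])
      prop <- cur + eps
      lamB <- lam[, B, drop = FALSE]
      dll <- D[, B, drop = FALSE] * eps - lamB * expm1(eps)
      # AR(1) prior delta; neighbours sit in the other parity, so fixed
      mu_prev <- matrix(0, U, nb)
      sdsq <- rep(sigma^2, nb)
      sdsq[first] <- s1sq
      if (any(!first)) {
        mu_prev[, !first] <- rho * theta[, B[!first] - 1, drop = FALSE]
      }
      dpr <- sweep((cur - mu_prev)^2 - (prop - mu_prev)^2, 2, 2 * sdsq, "/")
      if (any(has_next)) {
        nxt <- theta[, B[has_next] + 1, drop = FALSE]
        dpr[, has_next] <- dpr[, has_next, drop = FALSE] +
          ((nxt - rho * cur[, has_next, drop = FALSE])^2 -
             (nxt - rho * prop[, has_next, drop = FALSE])^2) / (2 * sigma^2)
      }
      lr <- dll + dpr
      acc <- matrix(log(runif(U * nb)), U) < lr
      if (any(acc)) {
        cur[acc] <- prop[acc]
        theta[, B] <- cur
        lamB[acc] <- lamB[acc] * exp(eps[acc])
        lam[, B] <- lamB
      }
      if (adapting) {
        ls_theta[, B] <- ls_theta[, B, drop = FALSE] +
          gam * (pmin(1, exp(lr)) - target)
      }

      ## recentering: alpha_a + c, theta[.,a] - c leaves the likelihood
      ## unchanged; accepted on the prior ratio alone
      cs <- rnorm(nb) * exp(ls_shift[B])
      sh <- theta[, B, drop = FALSE]
      shifted <- sweep(sh, 2, cs, "-")
      dpr <- (alpha[B]^2 - (alpha[B] + cs)^2) / (2 * pa_sd^2)
      mu_prev[] <- 0
      if (any(!first)) {
        mu_prev[, !first] <- rho * theta[, B[!first] - 1, drop = FALSE]
      }
      dpr <- dpr + colSums((sh - mu_prev)^2 - (shifted - mu_prev)^2) / (2 * sdsq)
      if (any(has_next)) {
        nxt <- theta[, B[has_next] + 1, drop = FALSE]
        dpr[has_next] <- dpr[has_next] +
          colSums((nxt - rho * sh[, has_next, drop = FALSE])^2 -
                    (nxt - rho * shifted[, has_next, drop = FALSE])^2) /
          (2 * sigma^2)
      }
      acc <- log(runif(nb)) < dpr
      if (any(acc)) {
        alpha[B[acc]] <- alpha[B[acc]] + cs[acc]
        theta[, B[acc]] <- shifted[, acc, drop = FALSE]
      }
      if (adapting) ls_shift[B] <- ls_shift[B] + gam * (pmin(1, exp(dpr)) - target)
    }

    ## rho update (transformed scale, Jacobian log(1 - rho^2))
    sigma <- exp(lsig)
    prop_t <- rho_t + rnorm(1) * exp(ls_rho)
    lr <- ar1_logprior(theta, tanh(prop_t), sigma) + log(1 - tanh(prop_t)^2) -
      (ar1_logprior(theta, tanh(rho_t), sigma) + log(1 - tanh(rho_t)^2))
    if (is.finite(lr) && log(runif(1)) < lr) rho_t <- prop_t
    if (adapting) ls_rho <- ls_rho + gam * (min(1, exp(lr)) - target)

    ## sigma update (log scale; Half-Normal prior + Jacobian)
    prop_s <- lsig + rnorm(1) * exp(ls_sig)
    rho <- tanh(rho_t)
    lr <- ar1_logprior(theta, rho, exp(prop_s)) +
      dnorm(exp(prop_s), 0, ps, log = TRUE) + prop_s -
      (ar1_logprior(theta, rho, exp(lsig)) +
         dnorm(exp(lsig), 0, ps, log = TRUE) + lsig)
    if (is.finite(lr) && log(runif(1)) < lr) lsig <- prop_s
    if (adapting) ls_sig <- ls_sig + gam * (min(1, exp(lr)) - target)

    if (it %% 1000 == 0) lam <- PY * exp(sweep(theta, 2, alpha, "+"))

    if (!adapting) {
      post_it <- it - config$burn_in
      alpha_trace[post_it, ] <- alpha
      rho_trace[post_it] <- tanh(rho_t)
      sig_trace[post_it] <- exp(lsig)
      if (k < n_keep && post_it == keep_idx[k + 1L]) {
        k <- k + 1L
        rates[k, , ] <- exp(sweep(theta, 2, alpha, "+"))
        rho_keep[k] <- tanh(rho_t)
        sigma_keep[k] <- exp(lsig)
      }
    }
  }
  list(rates = rates[seq_len(k), , , drop = FALSE],
       rho_keep = rho_keep[seq_len(k)], sigma_keep = sigma_keep[seq_len(k)],
       alpha_trace = alpha_trace, rho_trace = rho_trace, sig_trace = sig_trace)
}

# Split-chain Rhat and a simple autocovariance-based ESS.
split_rhat <- function(traces) {
  # traces: list of numeric vectors (one per chain)
  halves <- unlist(lapply(traces, function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars); B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(traces) {
  v <- unlist(traces)
  n <- length(v)
  if (var(v) == 0) return(n)
  # pooled chain ACF up to first negative pair sum (Geyer-style, simplified)
  acfs <- lapply(traces, function(x) {
    stats::acf(x, lag.max = min(200, length(x) - 1), plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  })
  rho <- Reduce(`+`, acfs) / length(acfs)
  s <- 0
  for (k in seq(2, length(rho) - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

smoothing_diagnostics <- function(chains, A) {
  params <- c(paste0("alpha[", seq_len(A), "]"), "rho", "sigma")
  get_traces <- function(i) {
    if (i <= A) lapply(chains, function(ch) ch$alpha_trace[, i])
    else if (i == A + 1) lapply(chains, `[[`, "rho_trace")
    else lapply(chains, `[[`, "sig_trace")
  }
  tibble::tibble(
    param = params,
    rhat = vapply(seq_along(params), function(i) split_rhat(get_traces(i)), 0),
    ess = vapply(seq_along(params), function(i) ess_basic(get_traces(i)), 0)
  )
}

#' @export
print.lexgap_smooth <- function(x, ...) {
  cat("<lexgap_smooth> ", dim(x$draws)[1], " draws x ", length(x$unit_ids),
      " units x ", dim(x$draws)[3], " age groups (sex: ", x$sex, ")\n",
      "max Rhat: ", round(max(x$diagnostics$rhat, na.rm = TRUE), 3), "\n",
      sep = "")
  invisible(x)
}

#' Posterior summary of smoothed rates
#'
#' Element-wise median and central 95% interval of the posterior rate
#' draws, per unit and age group.
#'
#' @param fit A `lexgap_smooth` object.
#' @return A tibble: `unit_id, sex, age_lower, rate_median, rate_lo95,
#'   rate_hi95`.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "lexgap_smooth"))
  qs <- apply(fit$draws, c(2, 3), quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  tibble::tibble(
    unit_id = rep(fit$unit_ids, times = dim(fit$draws)[3]),
    sex = fit$sex,
    age_lower = rep(fit$scheme$lower, each = length(fit$unit_ids)),
    rate_median = as.vector(qs[1, , ]),
    rate_lo95 = as.vector(qs[2, , ]),
    rate_hi95 = as.vector(qs[3, , ])
  ) |>
    dplyr::arrange(.data$unit_id, .data$age_lower)
}

#' Long-format posterior rate draws
#'
#' @param x A `lexgap_smooth` object.
#' @param ... Unused.
#' @return A tibble `draw, unit_id, sex, age_lower, rate`.
#' @export
tidy.lexgap_smooth <- function(x, ...) {
  d <- dim(x$draws)
  tibble::tibble(
    draw = rep(seq_len(d[1]), times = d[2] * d[3]),
    unit_id = rep(rep(x$unit_ids, each = d[1]), times = d[3]),
    sex = x$sex,
    age_lower = rep(x$scheme$lower, each = d[1] * d[2]),
    rate = as.vector(x$draws)
  )
}

#' One-row convergence overview of a smoothing fit
#'
#' @param x A `lexgap_smooth` object.
#' @param ... Unused.
#' @return A tibble with draw counts, max Rhat and min ESS.
#' @export
glance.lexgap_smooth <- function(x, ...) {
  tibble::tibble(
    n_draws = dim(x$draws)[1],
    n_units = length(x$unit_ids),
    n_age_groups = dim(x$draws)[3],
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}

#' @importFrom stats dnorm acf
NULL
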