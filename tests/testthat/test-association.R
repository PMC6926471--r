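test_that("exposure scaling matches the independent quantile computation", {
  set.seed(71)
  ses <- rbeta(30, 3, 5)
  w <- runif(30, 1, 20)
  scaled <- scale_exposure(ses, w)
  rng <- weighted_quantile(ses, w, 0.9) - weighted_quantile(ses, w, 0.1)
  expect_equal(as.numeric(scaled), ses / rng)
  expect_equal(attr(scaled, "p90_p10_range"), rng)
  # idempotence: the scaled exposure has weighted P90-P10 range 1
  rng2 <- weighted_quantile(as.numeric(scaled), w, 0.9) -
    weighted_quantile(as.numeric(scaled), w, 0.1)
  expect_equal(rng2, 1)
  # linearity of the regression coefficient under scaling
  y <- 70 + 5 * ses + rnorm(30, 0, 0.5)
  raw <- fit_wls(y, ses, weights = w)$coefficient
  sc <- fit_wls(y, as.numeric(scaled), weights = w)$coefficient
  expect_equal(sc, raw * rng, tolerance = 1e-10)
  expect_error(scale_exposure(rep(0.4, 5)), "constant")
})

test_that("fit_wls recovers exact linear structure and handles weights correctly", {
  set.seed(72)
  n <- 25
  ses <- runif(n); bu <- runif(n); w <- sample(1:5, n, replace = TRUE)
  y <- 10 + 3 * ses + 0.5 * bu
  f <- fit_wls(y, ses, builtup = bu, weights = w)
  expect_equal(f$coefficient, 3, tolerance = 1e-10)

  # integer weights equal duplicated-row unweighted fit
  y2 <- y + rnorm(n)
  f_w <- fit_wls(y2, ses, builtup = bu, weights = w)
  idx <- rep(seq_len(n), times = w)
  f_dup <- fit_wls(y2[idx], ses[idx], builtup = bu[idx])
  expect_equal(f_w$coefficient, f_dup$coefficient, tolerance = 1e-10)

  # permutation invariance
  perm <- sample(n)
  f_p <- fit_wls(y2[perm], ses[perm], builtup = bu[perm], weights = w[perm])
  expect_equal(f_p$coefficient, f_w$coefficient, tolerance = 1e-12)

  # matches lm() coefficient and classical variance
  lmfit <- lm(y2 ~ ses + bu, weights = w)
  expect_equal(f_w$coefficient, unname(coef(lmfit)["ses"]), tolerance = 1e-10)
  expect_equal(f_w$variance, vcov(lmfit)["ses", "ses"], tolerance = 1e-10)

  expect_error(fit_wls(y2, ses, builtup = ses * 2, weights = w), "collinear")
})

test_that("Rubin pooling reproduces the hand-computed example and identities", {
  p <- rubin_pool(c(1, 2, 3), c(0.25, 0.25, 0.25))
  expect_equal(p$qbar, 2)
  expect_equal(p$W, 0.25)
  expect_equal(p$B, 1)
  expect_equal(p$T, 0.25 + (1 + 1 / 3) * 1)
  expect_equal(p$se, sqrt(p$T))
  expect_equal(p$df, 2 * (1 + 0.25 / ((4 / 3) * 1))^2)
  expect_equal(unname(p$ci95), p$qbar + c(-1, 1) * qt(0.975, p$df) * p$se)

  # identical draws: B = 0, T = v, normal interval
  p0 <- rubin_pool(rep(1.7, 10), rep(0.04, 10))
  expect_equal(p0$qbar, 1.7)
  expect_equal(p0$B, 0)
  expect_equal(p0$T, 0.04)
  expect_equal(unname(p0$ci95), 1.7 + c(-1, 1) * qnorm(0.975) * 0.2)

  # order invariance and variance inflation
  set.seed(73)
  cf <- rnorm(50); vr <- runif(50, 0.1, 0.3)
  perm <- sample(50)
  expect_equal(rubin_pool(cf, vr)$T, rubin_pool(cf[perm], vr[perm])$T)
  expect_gte(rubin_pool(cf, vr)$T, max(rubin_pool(cf, vr)$W))

  td <- tidy(p)
  expect_equal(td$estimate, 2)
  expect_equal(glance(p)$m, 3)
})

test_that("pooled coefficient equals the draw-averaged-outcome coefficient (linearity)", {
  set.seed(74)
  n <- 20; m <- 30
  ses <- runif(n); bu <- runif(n); w <- runif(n, 1, 4)
  draws <- matrix(70 + 4 * ses + 0.3 * bu, n, m) + matrix(rnorm(n * m), n, m)
  per <- apply(draws, 2, function(y) fit_wls(y, ses, builtup = bu, weights = w)$coefficient)
  pooled <- rubin_pool(per, rep(0.1, m))
  avg_fit <- fit_wls(rowMeans(draws), ses, builtup = bu, weights = w)
  expect_equal(pooled$qbar, avg_fit$coefficient, tolerance = 1e-10)
})

test_that("association_pipeline recovers a known SES gradient and the null", {
  # known gradient: e0 constructed directly from SES with noise
  set.seed(75)
  sim <- simulate_cities(n_cities = 1, seed = 75, n_units = 25)
  units <- add_mean_population(sim$units, sim$population)
  beta_true <- 4  # years per P90-P10 education within the city
  sx <- scale_exposure(units$education, units$mean_population)
  draws <- tidyr::expand_grid(draw = 1:40, unit_id = units$unit_id, sex = "female")
  draws <- dplyr::left_join(draws, tibble::tibble(unit_id = units$unit_id,
                                                  sx = as.numeric(sx),
                                                  bu = units$builtup),
                            by = "unit_id")
  draws$e0 <- 70 + beta_true * draws$sx + 0.5 * draws$bu +
    rnorm(nrow(draws), 0, 0.4)
  out <- association_pipeline(draws, units, exposure = "education")
  expect_equal(nrow(out), 1)
  expect_true(out$lo95 < beta_true && beta_true < out$hi95)
  expect_lt(abs(out$coef - beta_true), 1)

  # degenerate: one draw duplicated m times pools to that draw's fit
  d1 <- draws[draws$draw == 1, ]
  dup <- dplyr::bind_rows(lapply(1:5, function(i) {
    d1$draw <- i; d1
  }))
  out_dup <- association_pipeline(dup, units, exposure = "education")
  one <- fit_wls(d1$e0, d1$sx, builtup = d1$bu,
                 weights = units$mean_population[match(d1$unit_id, units$unit_id)])
  expect_equal(out_dup$coef, one$coefficient, tolerance = 1e-10)

  # spatial adjustment leaves the coefficient near-unchanged when
  # coordinates are independent of SES and mortality
  out_sp <- association_pipeline(draws, units, exposure = "education",
                                 spatial_adjust = TRUE)
  expect_lt(abs(out_sp$coef - out$coef), 0.75)
})
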