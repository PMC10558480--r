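test_that("dates map to acquisition seasons with the winter-spanning year rule", {
  out <- season_of_date(c("2014-03-15", "2013-11-01", "2014-01-31",
                          "2014-05-01", "2014-08-31", "2014-12-25"))
  expect_equal(as.character(out$season),
               c("spring", "winter", "winter", "summer", "autumn", "winter"))
  expect_equal(out$cohort_year, c(2014L, 2013L, 2013L, 2014L, 2014L, 2014L))
  expect_error(season_of_date("not-a-date"), "invalid")
})

test_that("season ANOVA matches a hand-computed sum-of-squares oracle", {
  d <- tibble::tibble(
    v = c(1, 2, 1, 2, 5, 6, 5, 6),
    season = rep(season_levels(), each = 2)
  )
  an <- anova_seasons(d, v)
  # oracle: explicit SS decomposition
  gm <- mean(d$v)
  means <- tapply(d$v, d$season, mean)
  ss_b <- sum(2 * (means - gm)^2)
  ss_w <- sum((d$v - means[as.character(d$season)])^2)
  f_oracle <- (ss_b / 3) / (ss_w / 4)
  expect_equal(an$f_statistic, f_oracle)
  expect_equal(an$p_value, pf(f_oracle, 3, 4, lower.tail = FALSE))
  eta2 <- ss_b / (ss_b + ss_w)
  expect_equal(an$cohens_f, sqrt(eta2 / (1 - eta2)))
  # equal group means: F = 0, f = 0
  d0 <- tibble::tibble(v = rep(c(1, 2), 4), season = rep(season_levels(), each = 2))
  an0 <- anova_seasons(d0, v)
  expect_equal(an0$f_statistic, 0)
  expect_equal(an0$cohens_f, 0)
  expect_error(anova_seasons(d0[1:2, ], v), "two nonempty")
  expect_error(
    anova_seasons(tibble::tibble(v = rep(1, 8), season = d0$season), v),
    "zero total variance"
  )
})

test_that("ANOVA p-values are uniform under label permutation", {
  set.seed(41)
  d <- tibble::tibble(v = rnorm(48), season = rep(season_levels(), each = 12))
  ps <- replicate(2000, {
    anova_seasons(dplyr::mutate(d, season = sample(season)), v)$p_value
  })
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.2)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("pairwise contrasts reproduce the pooled-t hand computation", {
  d <- tibble::tibble(v = c(1, 2, 3, 4),
                      season = c("winter", "winter", "summer", "summer"))
  pw <- pairwise_seasons(d, v, "winter", "summer")
  # pooled SD = sqrt(0.5); d = -2 / sqrt(0.5) = -2.828; t = d * sqrt(n*n/(n+n))
  expect_equal(pw$cohens_d, -2 / sqrt(0.5))
  expect_equal(pw$t_stat, -2.828, tolerance = 1e-3)
  expect_equal(pw$df, 2)
  # antisymmetry under swapping the seasons
  pw2 <- pairwise_seasons(d, v, "summer", "winter")
  expect_equal(pw2$cohens_d, -pw$cohens_d)
  expect_equal(pw2$t_stat, -pw$t_stat)
  expect_equal(pw2$p_value, pw$p_value)
  # identical groups: t = 0, d = 0
  d3 <- tibble::tibble(v = c(1, 2, 1, 2),
                       season = c("winter", "winter", "summer", "summer"))
  pw3 <- pairwise_seasons(d3, v, "winter", "summer")
  expect_equal(pw3$t_stat, 0)
  expect_equal(pw3$cohens_d, 0)
  expect_error(pairwise_seasons(d, v, "winter", "spring"), "two subjects")
})

test_that("cosinor fit solves the single-observation system exactly", {
  d <- tibble::tibble(y = c(3, 2, 1, 2), season = season_levels())
  fit <- suppressWarnings(fit_seasonal_sinusoid(d, y))
  expect_equal(fit$a, 0, tolerance = 1e-10)
  expect_equal(fit$b, 1, tolerance = 1e-10)
  expect_equal(fit$c, 2, tolerance = 1e-10)
  expect_equal(fit$amplitude, 1, tolerance = 1e-10)
  expect_equal(fit$phase, 0, tolerance = 1e-10)
  expect_equal(fit$peak_season, "winter")
  expect_equal(sum(stats::residuals(fit$model)^2), 0, tolerance = 1e-20)
  # constant input: zero amplitude, zero F
  fit0 <- suppressWarnings(
    fit_seasonal_sinusoid(tibble::tibble(y = rep(5, 4), season = season_levels()), y)
  )
  expect_equal(fit0$amplitude, 0, tolerance = 1e-12)
  expect_equal(fit0$f_statistic, 0)
  expect_error(
    fit_seasonal_sinusoid(
      tibble::tibble(y = 1:4, season = rep(c("winter", "summer"), 2)), y
    ),
    "3 distinct seasons"
  )
})

test_that("amplitude/phase reconstruction identity holds on random fits", {
  set.seed(42)
  w <- pi / 2
  for (r in 1:20) {
    d <- tibble::tibble(y = rnorm(40),
                        season = sample(season_levels(), 40, replace = TRUE))
    if (length(unique(d$season)) < 3) next
    fit <- fit_seasonal_sinusoid(d, y)
    t <- 0:3
    recon <- fit$amplitude * cos(w * t + fit$phase) + fit$c
    direct <- fit$a * sin(w * t) + fit$b * cos(w * t) + fit$c
    expect_equal(recon, direct, tolerance = 1e-10)
    expect_gte(fit$amplitude, 0)
    expect_true(fit$phase > -pi && fit$phase <= pi)
    # mesor equals the OLS intercept; for balanced single-obs data it is the
    # grand mean (sin/cos columns sum to zero over t = 0..3)
  }
  d_bal <- tibble::tibble(y = c(4, 1, 7, 3), season = season_levels())
  fit_bal <- suppressWarnings(fit_seasonal_sinusoid(d_bal, y))
  expect_equal(fit_bal$c, mean(d_bal$y), tolerance = 1e-10)
})

test_that("cosinor recovery at moderate SNR matches closed-form expectations", {
  # n = 100/season, A_true = 0.1 on unit noise: the OLS coefficients have
  # sd sqrt(1/200), so the amplitude estimate is Rice-distributed with
  # E[A_hat] ~ 0.128 and the F-test has noncentrality 2 (power ~ 0.22).
  # The Monte-Carlo mean must match those independent closed forms.
  set.seed(43)
  theta <- phase_for_peak("autumn")
  n <- 100
  seasons <- rep(season_levels(), each = n)
  mu <- 0.1 * cos(pi / 2 * rep(0:3, each = n) + theta)
  sims <- replicate(200, {
    d <- tibble::tibble(y = mu + rnorm(4 * n), season = seasons)
    f <- fit_seasonal_sinusoid(d, y)
    c(f$amplitude,
      abs(atan2(sin(f$phase - theta), cos(f$phase - theta))),
      f$p_value < 0.05)
  })
  sig <- sqrt(1 / (2 * n))
  x <- 0.1^2 / (2 * sig^2)
  laguerre_half <- exp(-x / 2) *
    ((1 + x) * besselI(x / 2, 0) + x * besselI(x / 2, 1))
  rice_mean <- sig * sqrt(pi / 2) * laguerre_half
  expect_equal(mean(sims[1, ]), rice_mean, tolerance = 0.05)
  # noncentrality: sum_s n * (A cos(w t_s + theta))^2 = 2 n A^2
  power_oracle <- pf(qf(0.95, 2, 4 * n - 3), 2, 4 * n - 3,
                     ncp = 2 * n * 0.1^2, lower.tail = FALSE)
  expect_equal(mean(sims[3, ]), power_oracle, tolerance = 0.25)
})

test_that("environmental regression recovers exact linear structure", {
  cfg <- simulation_config(n_per_season = c(1, 1, 1, 1), n_gm_regions = 2,
                           n_wm_regions = 1, n_networks = 1,
                           n_timepoints = 16, seed = 44)
  env <- generate_environment(cfg)
  set.seed(45)
  d <- tibble::tibble(
    season = sample(season_levels(), 60, replace = TRUE),
    year = sample(2013:2015, 60, replace = TRUE)
  )
  key <- paste(d$season, d$year)
  envkey <- paste(env$season, env$year)
  d$v <- 0.5 * env$mean_temperature[match(key, envkey)] +
    0.1 * env$mean_daylength[match(key, envkey)] + 2
  # exact recovery triggers R's "essentially perfect fit" note, by design
  fit <- suppressWarnings(environmental_regression(d, v, env = env))
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(unname(est["temperature"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(est["daylength"]), 0.1, tolerance = 1e-8)
  expect_equal(unname(est["(Intercept)"]), 2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # flat environment is rank-deficient
  env0 <- generate_environment(cfg, temperature_amplitude = 0,
                               temperature_year_sd = 0,
                               daylength_amplitude = 0)
  expect_error(environmental_regression(d, v, env = env0), "collinear")
  # missing season-years are reported
  expect_error(environmental_regression(d, v, env = env[1:2, ]), "missing")
})

test_that("environmental regression is calibrated under the null", {
  cfg <- simulation_config(n_per_season = c(1, 1, 1, 1), n_gm_regions = 2,
                           n_wm_regions = 1, n_networks = 1,
                           n_timepoints = 16, seed = 46)
  env <- generate_environment(cfg)
  set.seed(47)
  d0 <- tibble::tibble(
    season = sample(season_levels(), 80, replace = TRUE),
    year = sample(2013:2015, 80, replace = TRUE)
  )
  rej <- replicate(500, {
    d0$v <- rnorm(80)
    environmental_regression(d0, v, env = env)$p_value < 0.05
  })
  expect_equal(mean(rej), 0.05, tolerance = 0.5)
})

test_that("group summaries report means and standard errors per season", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6, 7, 8),
                      season = rep(season_levels(), each = 2))
  gs <- season_group_summary(d, v)
  expect_equal(as.character(gs$season), season_levels())
  expect_equal(gs$mean, c(1.5, 3.5, 5.5, 7.5))
  expect_equal(gs$sem, rep(sd(c(1, 2)) / sqrt(2), 4))
  d2 <- tibble::tibble(v = c(1, 2, 3), season = c("winter", "winter", "summer"))
  expect_warning(gs2 <- season_group_summary(d2, v), "singleton")
  expect_true(is.na(gs2$sem[gs2$season == "summer"]))
  # single value per group: means pass through
  expect_equal(suppressWarnings(
    season_group_summary(tibble::tibble(v = c(1, 2, 3),
                                        season = c("winter", "spring", "summer")), v)$mean
  ), c(1, 2, 3))
  # hand check: group (1,2,3) -> mean 2, SEM 1/sqrt(3)
  d4 <- tibble::tibble(v = c(1, 2, 3, 9, 9), season = c(rep("winter", 3), "spring", "spring"))
  gs4 <- season_group_summary(d4, v)
  expect_equal(gs4$mean[1], 2)
  expect_equal(gs4$sem[1], 1 / sqrt(3))
})

test_that("cosinor and ANOVA agree directionally on injected seasonal effects", {
  set.seed(48)
  n <- 50
  seasons <- rep(season_levels(), each = n)
  mu_big <- 0.5 * cos(pi / 2 * rep(0:3, each = n) + phase_for_peak("autumn"))
  both_reject <- replicate(30, {
    d <- tibble::tibble(y = mu_big + rnorm(4 * n), season = seasons)
    anova_seasons(d, y)$p_value < 0.05 &&
      fit_seasonal_sinusoid(d, y)$p_value < 0.05
  })
  expect_gt(mean(both_reject), 0.8)
})

test_that("tidy and glance methods expose the fitted quantities", {
  set.seed(49)
  d <- tibble::tibble(y = rnorm(40), season = rep(season_levels(), 10))
  fit <- fit_seasonal_sinusoid(d, y)
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("mesor", "sin", "cos"))
  gl <- generics::glance(fit)
  expect_equal(gl$amplitude, fit$amplitude)
  an <- anova_seasons(d, y)
  expect_equal(generics::glance(an)$f_statistic, an$f_statistic)
  expect_s3_class(generics::tidy(an), "tbl_df")
})
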