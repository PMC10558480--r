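test_that("seasonal gain follows the quarter-coded cosine and stays positive", {
  # zero amplitude is the identity for any season/phase
  expect_equal(seasonal_gain(0:3, amp = 0, phase = 1.3), rep(1, 4))
  # autumn-peak phase: gain 1 + amp at autumn, 1 - amp at the opposite quarter
  expect_equal(seasonal_gain(3, amp = 0.2, phase = -3 * pi / 2), 1.2)
  expect_equal(seasonal_gain(1, amp = 0.2, phase = -3 * pi / 2), 0.8)
  expect_equal(
    seasonal_gain(0:3, 0.2, phase_for_peak("autumn")),
    seasonal_gain(0:3, 0.2, -3 * pi / 2)
  )
  for (s in season_levels()) {
    g <- seasonal_gain(0:3, 0.5, phase_for_peak(s))
    expect_equal(season_levels()[which.max(g)], s)
  }
  expect_gt(min(seasonal_gain(0:3, amp = 0.99, phase = 0)), 0)
  expect_error(seasonal_gain(2, amp = 1, phase = 0), "amp")
  expect_error(seasonal_gain(5, amp = 0.1, phase = 0), "season_index")
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(amp_true = 1), "amp_true")
  expect_error(simulation_config(n_timepoints = 8), "n_timepoints")
  expect_error(simulation_config(tr_seconds = 0), "tr_seconds")
  expect_error(simulation_config(n_per_season = c(1, 2, 3)), "n_per_season")
  expect_error(simulation_config(n_per_season = c(-1, 2, 3, 4)))
  expect_error(
    generate_cohort(simulation_config(n_per_season = c(0, 0, 0, 0))),
    "zero"
  )
})

test_that("generated cohorts carry the configured season composition", {
  co <- generate_cohort(simulation_config(
    n_per_season = c(127, 99, 91, 93),
    n_gm_regions = 3, n_wm_regions = 2, n_networks = 1,
    n_timepoints = 16, n_latents = 1, seed = 5
  ))
  counts <- table(co$subjects$season)
  expect_equal(unname(c(counts)), c(127, 99, 91, 93))
  expect_equal(nrow(co$subjects), 410)
  expect_false(anyDuplicated(co$subjects$id) > 0)
  expect_true(all(co$subjects$sex %in% c("F", "M")))
  # winter carries the starting year of its cycle, other seasons the next one
  expect_true(all(co$subjects$year[co$subjects$season == "winter"]
                  %in% c(2013, 2014)))
  expect_true(all(co$subjects$year[co$subjects$season != "winter"]
                  %in% c(2014, 2015)))
})

test_that("identical configurations generate bit-identical cohorts", {
  cfg <- simulation_config(
    n_per_season = c(2, 2, 2, 2), n_gm_regions = 3, n_wm_regions = 2,
    n_networks = 1, n_timepoints = 64, n_latents = 2,
    amp_true = 0.2, phase_true = 1, seed = 77
  )
  expect_identical(
    serialize(generate_cohort(cfg), NULL),
    serialize(generate_cohort(cfg), NULL)
  )
  # a different seed changes the signals
  cfg2 <- simulation_config(
    n_per_season = c(2, 2, 2, 2), n_gm_regions = 3, n_wm_regions = 2,
    n_networks = 1, n_timepoints = 64, n_latents = 2,
    amp_true = 0.2, phase_true = 1, seed = 78
  )
  expect_false(identical(generate_cohort(cfg)$series[[1]],
                         generate_cohort(cfg2)$series[[1]]))
})

test_that("injected seasonal gain raises autumn low-frequency power and scales with amplitude", {
  # Monte-Carlo: mean fALFF contrast autumn (gain peak) vs spring (trough)
  # must be positive and strictly increase over an amplitude grid
  contrast_for <- function(amp, seed) {
    co <- make_test_cohort(
      n_per_season = c(0, 8, 0, 8), n_gm = 4, n_wm = 2, n_networks = 1,
      n_timepoints = 256, amp = amp, phase = phase_for_peak("autumn"),
      seed = seed
    )
    fal <- cohort_falff(co)
    mean(fal$falff_gm[fal$season == "autumn"]) -
      mean(fal$falff_gm[fal$season == "spring"])
  }
  grid <- c(0, 0.3, 0.6)
  contrasts <- sapply(grid, function(a) {
    mean(sapply(1:12, function(r) contrast_for(a, seed = 300 + r)))
  })
  expect_true(all(diff(contrasts) > 0))
  expect_gt(contrasts[3], 0.05)
})

test_that("environment table peaks at the requested season and respects bounds", {
  cfg <- simulation_config(n_per_season = c(1, 1, 1, 1), n_gm_regions = 2,
                           n_wm_regions = 1, n_networks = 1,
                           n_timepoints = 16, seed = 3)
  env <- generate_environment(cfg, peak_season_index = 2)
  by_season <- tapply(env$mean_daylength, env$season, mean)
  expect_equal(names(which.max(by_season)), "summer")
  expect_true(all(env$mean_daylength > 0 & env$mean_daylength < 24))
  # closed form: daylength mean 12, amplitude 3 -> winter 9, summer 15
  env2 <- generate_environment(cfg, peak_season_index = 2,
                               daylength_mean = 12, daylength_amplitude = 3)
  expect_equal(env2$mean_daylength[env2$season == "winter"][1], 9)
  expect_equal(env2$mean_daylength[env2$season == "summer"][1], 15)
  # zero amplitudes give constant rows
  env3 <- generate_environment(cfg, temperature_amplitude = 0,
                               temperature_year_sd = 0,
                               daylength_amplitude = 0)
  expect_equal(sd(env3$mean_temperature), 0)
  expect_equal(sd(env3$mean_daylength), 0)
  expect_error(
    generate_environment(cfg, daylength_mean = 23, daylength_amplitude = 3),
    "daylength"
  )
})
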