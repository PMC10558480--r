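#' Configuration of the synthetic seasonal BOLD cohort generator
#'
#' Defines the study conditions for simulated cohorts: four season groups with
#' (by default) the unbalanced sizes of the modelled study, region-averaged
#' BOLD-like signals of 1200 timepoints at TR = 0.72 s, a shared low-frequency
#' latent structure giving rise to inter-regional correlation, and a seasonal
#' gain that multiplies the band-limited latent component so that both fALFF
#' and functional connectivity are modulated by one amplitude parameter.
#'
#' @param n_per_season Named or positional counts for winter, spring, summer,
#'   autumn (default `c(127, 99, 91, 93)`).
#' @param n_gm_regions,n_wm_regions Numbers of gray-matter regions and
#'   white-matter bundles (defaults 90 and 48).
#' @param n_networks Number of functional networks the GM regions are assigned
#'   to, round-robin (default 14).
#' @param n_timepoints Timepoints per subject (default 1200, minimum 16).
#' @param tr_seconds Sampling interval in seconds (default 0.72).
#' @param n_latents Number of shared band-limited latent signals per subject.
#' @param loading_scale Standard deviation of the latent-to-region loadings;
#'   the default gives a latent (signal) component with variance roughly equal
#'   to the white-noise floor.
#' @param noise_sd Standard deviation of the additive white noise.
#' @param amp_true Seasonal gain amplitude in `[0, 1)`; 0 means no seasonal
#'   effect.
#' @param phase_true Seasonal gain phase in radians; see [phase_for_peak()].
#' @param sex_effect Additive offset applied (downstream, to derived measures)
#'   for male subjects, to exercise nuisance residualization.
#' @param p_female Probability a simulated subject is female (default 0.6).
#' @param years Two consecutive cohort years; each subject's season is
#'   assigned to one of them (default `c(2013, 2014)` for winter, shifted by
#'   one for the other seasons to emulate a winter-to-autumn span).
#' @param seed Integer master seed; identical configurations (including the
#'   seed) generate bit-identical cohorts.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_per_season = c(4, 4, 4, 4),
#'                          n_gm_regions = 6, n_wm_regions = 4,
#'                          n_timepoints = 128, seed = 1)
simulation_config <- function(n_per_season = c(127, 99, 91, 93),
                              n_gm_regions = 90,
                              n_wm_regions = 48,
                              n_networks = 14,
                              n_timepoints = 1200,
                              tr_seconds = 0.72,
                              n_latents = 8,
                              loading_scale = 1.1,
                              noise_sd = 1,
                              amp_true = 0,
                              phase_true = 0,
                              sex_effect = 0,
                              p_female = 0.6,
                              years = c(2013, 2014),
                              seed = 1L) {
  if (length(n_per_season) != 4 || anyNA(n_per_season)) {
    abort("`n_per_season` must give four counts (winter, spring, summer, autumn)")
  }
  n_per_season <- vapply(seq_along(n_per_season), function(i) {
    assert_count(n_per_season[[i]], "n_per_season")
  }, integer(1))
  names(n_per_season) <- season_levels()
  cfg <- list(
    n_per_season = n_per_season,
    n_gm_regions = assert_count(n_gm_regions, "n_gm_regions", min = 1L),
    n_wm_regions = assert_count(n_wm_regions, "n_wm_regions", min = 1L),
    n_networks = assert_count(n_networks, "n_networks", min = 1L),
    n_timepoints = assert_count(n_timepoints, "n_timepoints", min = 16L),
    tr_seconds = assert_scalar_number(tr_seconds, "tr_seconds"),
    n_latents = assert_count(n_latents, "n_latents", min = 1L),
    loading_scale = assert_scalar_number(loading_scale, "loading_scale"),
    noise_sd = assert_scalar_number(noise_sd, "noise_sd"),
    amp_true = assert_scalar_number(amp_true, "amp_true"),
    phase_true = assert_scalar_number(phase_true, "phase_true"),
    sex_effect = assert_scalar_number(sex_effect, "sex_effect"),
    p_female = assert_scalar_number(p_female, "p_female"),
    years = years,
    seed = assert_count(seed, "seed")
  )
  if (cfg$tr_seconds <= 0) abort("`tr_seconds` must be positive")
  if (cfg$amp_true < 0 || cfg$amp_true >= 1) {
    abort("`amp_true` must lie in [0, 1) so the seasonal gain stays positive")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be nonnegative")
  if (cfg$p_female < 0 || cfg$p_female > 1) abort("`p_female` must be in [0, 1]")
  if (length(cfg$years) != 2 || any(cfg$years != as.integer(cfg$years))) {
    abort("`years` must be two integer years")
  }
  if (cfg$n_networks > cfg$n_gm_regions) {
    abort("`n_networks` cannot exceed `n_gm_regions`")
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf(
    "  subjects: %s (winter/spring/summer/autumn)\n",
    paste(x$n_per_season, collapse = "/")
  ))
  cat(sprintf(
    "  regions: %d GM + %d WM, %d networks; %d timepoints @ TR %.3g s\n",
    x$n_gm_regions, x$n_wm_regions, x$n_networks, x$n_timepoints, x$tr_seconds
  ))
  cat(sprintf(
    "  seasonal amp %.3g, phase %.3g rad; sex effect %.3g; seed %d\n",
    x$amp_true, x$phase_true, x$sex_effect, x$seed
  ))
  invisible(x)
}

#' Seasonal gain applied to the latent BOLD component
#'
#' The multiplicative gain `1 + amp * cos(2 * pi * season_index / 4 + phase)`
#' for quarter-coded seasons (winter = 0, ..., autumn = 3). With `amp < 1` the
#' gain is strictly positive.
#'
#' @param season_index Integer(s) in 0..3 (quarter code).
#' @param amp Gain amplitude, in `[0, 1)`.
#' @param phase Gain phase in radians.
#'
#' @return Numeric vector of strictly positive gains.
#' @export
#' @examples
#' seasonal_gain(0:3, amp = 0.2, phase = phase_for_peak("autumn"))
seasonal_gain <- function(season_index, amp, phase) {
  assert_scalar_number(amp, "amp")
  assert_scalar_number(phase, "phase")
  if (amp < 0 || amp >= 1) {
    abort("`amp` must lie in [0, 1): a gain could otherwise be non-positive")
  }
  if (any(!season_index %in% 0:3)) abort("`season_index` must be in 0..3")
  1 + amp * cos(2 * pi * season_index / 4 + phase)
}

#' Phase placing the seasonal-gain peak at a given season
#'
#' @param season One of `"winter"`, `"spring"`, `"summer"`, `"autumn"`, or a
#'   quarter code 0..3.
#'
#' @return Phase in `(-pi, pi]` such that [seasonal_gain()] is maximal at that
#'   season.
#' @export
phase_for_peak <- function(season) {
  code <- if (is.numeric(season)) {
    if (!season %in% 0:3) abort("`season` code must be in 0..3")
    as.integer(season)
  } else {
    season_code(season)
  }
  wrap_angle(-2 * pi * code / 4)
}

#' Generate a synthetic cohort of region-averaged BOLD time series
#'
#' For each subject, `n_latents` latent signals are drawn as white noise and
#' band-pass filtered to 0.01-0.08 Hz; the region signal is
#' `gain * (latents %*% loadings) + noise`, where the gain is
#' [seasonal_gain()] evaluated at the subject's acquisition season. Loadings
#' are drawn once per cohort so the connectivity backbone is shared across
#' subjects. Winter subjects carry the starting year of a season cycle that
#' spans the year boundary (November-January).
#'
#' @param config A [simulation_config()].
#'
#' @return An object of class `fc_cohort`: a list with elements `subjects`
#'   (tibble: id, sex, season, year), `regions` (tibble: region, tissue,
#'   network), `series` (named list of timepoints x regions matrices),
#'   `tr_seconds`, and `ground_truth` (the generating config).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be created by simulation_config()")
  }
  n_total <- sum(config$n_per_season)
  if (n_total == 0) abort("all season counts are zero; nothing to generate")

  seeds <- derive_seeds(config$seed, 2L + n_total)
  regions <- cohort_regions(config)
  n_regions <- nrow(regions)

  subjects <- tibble::tibble(
    id = sprintf("sub%04d", seq_len(n_total)),
    season = factor(
      rep(season_levels(), times = config$n_per_season),
      levels = season_levels()
    )
  )
  subjects <- with_seed(seeds[1], {
    subjects$sex <- ifelse(runif(n_total) < config$p_female, "F", "M")
    # each subject belongs to one of two winter-to-autumn cycles; winter spans
    # Nov-Jan and carries the starting year of its cycle, the remaining
    # seasons fall in the following calendar year
    cycle <- sample(c(0L, 1L), n_total, replace = TRUE)
    base_year <- as.integer(min(config$years))
    subjects$year <- base_year + cycle +
      ifelse(subjects$season == "winter", 0L, 1L)
    subjects
  })

  loadings <- with_seed(seeds[2], {
    matrix(
      rnorm(config$n_latents * n_regions, sd = config$loading_scale),
      config$n_latents, n_regions
    )
  })

  gains <- seasonal_gain(
    season_code(subjects$season),
    amp = config$amp_true, phase = config$phase_true
  )

  low <- 0.01
  high <- 0.08
  series <- vector("list", n_total)
  names(series) <- subjects$id
  for (i in seq_len(n_total)) {
    series[[i]] <- with_seed(seeds[2 + i], {
      latents <- matrix(
        rnorm(config$n_timepoints * config$n_latents),
        config$n_timepoints, config$n_latents
      )
      latents <- bandpass_filter(latents, config$tr_seconds, low, high)
      sig <- gains[i] * (latents %*% loadings)
      if (config$noise_sd > 0) {
        sig <- sig + matrix(
          rnorm(config$n_timepoints * n_regions, sd = config$noise_sd),
          config$n_timepoints, n_regions
        )
      }
      colnames(sig) <- regions$region
      sig
    })
  }

  new_fc_cohort(
    subjects = subjects[c("id", "sex", "season", "year")],
    regions = regions,
    series = series,
    tr_seconds = config$tr_seconds,
    ground_truth = config
  )
}

cohort_regions <- function(config) {
  gm <- tibble::tibble(
    region = sprintf("GM%03d", seq_len(config$n_gm_regions)),
    tissue = "GM",
    network = sprintf(
      "network%02d",
      rep_len(seq_len(config$n_networks), config$n_gm_regions)
    )
  )
  wm <- tibble::tibble(
    region = sprintf("WM%03d", seq_len(config$n_wm_regions)),
    tissue = "WM",
    network = NA_character_
  )
  dplyr::bind_rows(gm, wm)
}

new_fc_cohort <- function(subjects, regions, series, tr_seconds,
                          ground_truth = NULL) {
  if (anyDuplicated(subjects$id)) abort("subject ids must be unique")
  if (anyDuplicated(regions$region)) abort("region labels must be unique")
  if (!all(regions$tissue %in% c("GM", "WM"))) {
    abort("region tissue labels must be 'GM' or 'WM'")
  }
  if (!all(as.character(subjects$season) %in% season_levels())) {
    abort("subject seasons must be winter/spring/summer/autumn")
  }
  if (!setequal(names(series), subjects$id)) {
    abort("series must be named by subject id, one per subject")
  }
  for (id in subjects$id) {
    m <- series[[id]]
    if (!is.matrix(m) || !identical(colnames(m), regions$region)) {
      abort(paste0("series for ", id, " does not match the region table"))
    }
  }
  structure(
    list(
      subjects = tibble::as_tibble(subjects),
      regions = tibble::as_tibble(regions),
      series = series[subjects$id],
      tr_seconds = tr_seconds,
      ground_truth = ground_truth
    ),
    class = "fc_cohort"
  )
}

#' @export
print.fc_cohort <- function(x, ...) {
  n_gm <- sum(x$regions$tissue == "GM")
  n_wm <- sum(x$regions$tissue == "WM")
  counts <- table(x$subjects$season)
  cat("<fc_cohort>\n")
  cat(sprintf(
    "  %d subjects (%s), %d GM + %d WM regions, %d timepoints @ TR %.3g s\n",
    nrow(x$subjects),
    paste(sprintf("%s %d", names(counts), counts), collapse = ", "),
    n_gm, n_wm, nrow(x$series[[1]]), x$tr_seconds
  ))
  if (!is.null(x$ground_truth)) {
    cat(sprintf(
      "  simulated: amp %.3g, phase %.3g rad, sex effect %.3g, seed %d\n",
      x$ground_truth$amp_true, x$ground_truth$phase_true,
      x$ground_truth$sex_effect, x$ground_truth$seed
    ))
  }
  invisible(x)
}

#' Generate a seasonal environment table (temperature and daylength)
#'
#' One row per season-year present in a cohort generated from `config`.
#' Both variables follow `mean + amplitude * cos(2 * pi * (t - peak) / 4)`
#' over quarter codes t, peaking at `peak_season_index`. Daylength is
#' deterministic (it is astronomically fixed), while temperature receives
#' small seeded year-to-year deviations so the two regressors are not exactly
#' collinear across quarters.
#'
#' @param config A [simulation_config()]; supplies the cohort years and seed.
#' @param peak_season_index Quarter code 0..3 at which both series peak
#'   (default 2, summer).
#' @param temperature_mean,temperature_amplitude Seasonal mean and half-range
#'   of temperature in degrees Celsius (defaults 13.9 and 12, a temperate
#'   mid-latitude climate).
#' @param temperature_year_sd Standard deviation of the per-(season, year)
#'   temperature deviation (default 1.5 degrees C; 0 gives an exact cosine).
#' @param daylength_mean,daylength_amplitude Mean and half-range of daylength
#'   in hours (defaults 12.2 and 2.6); the implied range must stay within
#'   (0, 24).
#'
#' @return A tibble with columns `season`, `season_index`, `year`,
#'   `mean_temperature`, `mean_daylength`.
#' @export
generate_environment <- function(config,
                                 peak_season_index = 2L,
                                 temperature_mean = 13.9,
                                 temperature_amplitude = 12,
                                 temperature_year_sd = 1.5,
                                 daylength_mean = 12.2,
                                 daylength_amplitude = 2.6) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be created by simulation_config()")
  }
  if (!peak_season_index %in% 0:3) abort("`peak_season_index` must be in 0..3")
  assert_scalar_number(temperature_mean, "temperature_mean")
  assert_scalar_number(temperature_amplitude, "temperature_amplitude")
  assert_scalar_number(temperature_year_sd, "temperature_year_sd")
  assert_scalar_number(daylength_mean, "daylength_mean")
  assert_scalar_number(daylength_amplitude, "daylength_amplitude")
  if (temperature_year_sd < 0) abort("`temperature_year_sd` must be >= 0")
  dl_range <- daylength_mean + c(-1, 1) * abs(daylength_amplitude)
  if (dl_range[1] <= 0 || dl_range[2] >= 24) {
    abort("daylength parameters must keep daylength inside (0, 24) hours")
  }

  base_year <- as.integer(min(config$years))
  grid <- tidyr::expand_grid(
    season = factor(season_levels(), levels = season_levels()),
    year = base_year + 0:2  # covers both winter-to-autumn cycles
  )
  grid$season_index <- season_code(grid$season)
  phase <- 2 * pi * (grid$season_index - peak_season_index) / 4

  env_seed <- derive_seeds(config$seed + 10000L, 1L)
  jitter <- with_seed(env_seed, rnorm(nrow(grid), sd = temperature_year_sd))

  tibble::tibble(
    season = grid$season,
    season_index = grid$season_index,
    year = grid$year,
    mean_temperature = temperature_mean +
      temperature_amplitude * cos(phase) + jitter,
    mean_daylength = daylength_mean + daylength_amplitude * cos(phase)
  )
}
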