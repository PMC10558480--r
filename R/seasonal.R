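#' Acquisition season and cohort year of calendar dates
#'
#' Seasons follow the acquisition-quarter convention: spring is February 1 to
#' April 30, summer May 1 to July 31, autumn August 1 to October 31, and
#' winter November 1 to January 31. A winter therefore spans a year boundary:
#' November and December dates carry their own calendar year as the cohort
#' year, January dates the preceding one.
#'
#' @param date A `Date` vector, or anything `as.Date()` understands.
#'
#' @return A tibble with columns `date`, `season` (factor, winter first) and
#'   `cohort_year` (integer).
#' @export
#' @examples
#' season_of_date(c("2014-03-15", "2013-11-01", "2014-01-31"))
season_of_date <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) abort("invalid date(s)"))
  if (anyNA(d)) abort("invalid date(s)")
  m <- as.integer(format(d, "%m"))
  y <- as.integer(format(d, "%Y"))
  season <- dplyr::case_when(
    m %in% 2:4 ~ "spring",
    m %in% 5:7 ~ "summer",
    m %in% 8:10 ~ "autumn",
    TRUE ~ "winter"
  )
  cohort_year <- ifelse(m == 1L, y - 1L, y)
  tibble::tibble(
    date = d,
    season = factor(season, levels = season_levels()),
    cohort_year = as.integer(cohort_year)
  )
}

# pull value/season (and optional extras) out of a data frame with tidy-eval
seasonal_frame <- function(data, value, season) {
  v <- dplyr::pull(data, {{ value }})
  s <- dplyr::pull(data, {{ season }})
  if (!is.numeric(v)) abort("the measure column must be numeric")
  if (anyNA(v)) abort("the measure column contains missing values")
  sf <- factor(as.character(s), levels = season_levels())
  if (anyNA(sf)) {
    bad <- unique(as.character(s)[is.na(sf)])
    abort(paste0("unknown season(s): ", paste(bad, collapse = ", ")))
  }
  tibble::tibble(value = v, season = sf)
}

#' Per-season group mean and standard error
#'
#' @param data A data frame with one row per subject.
#' @param value Unquoted name of the numeric measure column.
#' @param season Unquoted name of the season column.
#'
#' @return A tibble ordered winter to autumn with columns `season`, `n`,
#'   `mean`, `sem` (`sd/sqrt(n)`; `NA` with a warning for singleton groups).
#' @export
season_group_summary <- function(data, value, season = season) {
  df <- seasonal_frame(data, {{ value }}, {{ season }})
  out <- df |>
    dplyr::group_by(season, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(value),
      sem = sd(value) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::filter(n > 0)
  if (any(out$n == 1)) {
    warn("standard error undefined for singleton season group(s); reported as NA")
  }
  out
}

#' One-way ANOVA of a measure across the four seasons
#'
#' Fixed-effects one-way ANOVA of the (nuisance-adjusted) per-subject measure
#' on season group, with Cohen's f computed as `sqrt(eta^2 / (1 - eta^2))`
#' where `eta^2 = SS_between / SS_total`.
#'
#' @inheritParams season_group_summary
#'
#' @return An object of class `season_anova` with [generics::glance()] /
#'   [generics::tidy()] methods; `glance()` gives `f_statistic`, `df1`,
#'   `df2`, `p_value`, `eta_squared`, `cohens_f`, `n`.
#' @export
anova_seasons <- function(data, value, season = season) {
  df <- seasonal_frame(data, {{ value }}, {{ season }})
  df$season <- droplevels(df$season)
  k <- nlevels(df$season)
  if (k < 2) abort("need at least two nonempty season groups")
  n <- nrow(df)
  if (n - k < 1) abort("no residual degrees of freedom")
  if (var(df$value) == 0) abort("measure has zero total variance")

  fit <- lm(value ~ season, data = df)
  an <- anova(fit)
  ss_b <- an[["Sum Sq"]][1]
  ss_w <- an[["Sum Sq"]][2]
  eta2 <- ss_b / (ss_b + ss_w)
  structure(
    list(
      f_statistic = an[["F value"]][1],
      df1 = an[["Df"]][1],
      df2 = an[["Df"]][2],
      p_value = an[["Pr(>F)"]][1],
      eta_squared = eta2,
      cohens_f = sqrt(eta2 / (1 - eta2)),
      n = n,
      groups = season_group_summary(df, value, season)
    ),
    class = "season_anova"
  )
}

#' @export
print.season_anova <- function(x, ...) {
  cat(sprintf(
    "Season one-way ANOVA: F(%d, %d) = %.4f, p = %.4g, Cohen's f = %.4f (n = %d)\n",
    x$df1, x$df2, x$f_statistic, x$p_value, x$cohens_f, x$n
  ))
  invisible(x)
}

#' Pairwise season contrast with Cohen's d
#'
#' Two-sample pooled-variance Student's t-test between two season groups;
#' Cohen's d is the mean difference (first minus second season) divided by
#' the pooled standard deviation, so its sign follows the mean difference
#' and flips when the seasons are swapped.
#'
#' @inheritParams season_group_summary
#' @param s1,s2 Season names to contrast (d and t are `s1` minus `s2`).
#'
#' @return A one-row tibble: `season_a`, `season_b`, `t_stat`, `df`,
#'   `p_value`, `cohens_d`, `mean_diff`.
#' @export
pairwise_seasons <- function(data, value, s1, s2, season = season) {
  df <- seasonal_frame(data, {{ value }}, {{ season }})
  s1 <- match.arg(s1, season_levels())
  s2 <- match.arg(s2, season_levels())
  if (s1 == s2) abort("`s1` and `s2` must differ")
  a <- df$value[df$season == s1]
  b <- df$value[df$season == s2]
  if (length(a) < 2 || length(b) < 2) {
    abort("both season groups need at least two subjects")
  }
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) abort("zero pooled variance; contrast undefined")
  tt <- t.test(a, b, var.equal = TRUE)
  tibble::tibble(
    season_a = s1,
    season_b = s2,
    t_stat = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    cohens_d = (mean(a) - mean(b)) / sqrt(sp2),
    mean_diff = mean(a) - mean(b)
  )
}

#' Cosinor fit of seasonal periodicity
#'
#' Fits the quarter-coded sinusoid `y = a sin(wt) + b cos(wt) + c` with
#' `t = 0, 1, 2, 3` for winter, spring, summer, autumn and `w = 2 pi / 4`,
#' by ordinary least squares on per-subject observations. The amplitude/phase
#' form is `y = A cos(wt + theta) + c` with `A = sqrt(a^2 + b^2)`,
#' `b = A cos(theta)`, `a = -A sin(theta)`, `theta` in `(-pi, pi]`. An F-test
#' of the sine and cosine terms jointly against the intercept-only model
#' (df 2 and n - 3) quantifies the significance of seasonal periodicity, and
#' Cohen's f is `sqrt(R^2 / (1 - R^2))`.
#'
#' @inheritParams season_group_summary
#' @param band_points Number of points of the continuous-time fitted curve
#'   and its 95 percent pointwise confidence band over `t` in `[0, 4)`.
#'
#' @return An object of class `seasonal_fit` with `tidy()`, `glance()` and
#'   `autoplot()` methods. Key elements: `a`, `b`, `c`, `amplitude`, `phase`,
#'   `f_statistic`, `df1`, `df2`, `p_value`, `cohens_f`, `band` (tibble `t`,
#'   `fit`, `lwr`, `upr`), `groups` (per-season summary), `peak_season`.
#' @export
#' @examples
#' d <- data.frame(y = c(3, 2, 1, 2),
#'                 season = c("winter", "spring", "summer", "autumn"))
#' fit <- fit_seasonal_sinusoid(d, y)
#' fit$amplitude  # 1
fit_seasonal_sinusoid <- function(data, value, season = season,
                                  band_points = 161L) {
  df <- seasonal_frame(data, {{ value }}, {{ season }})
  n <- nrow(df)
  if (n < 4) abort("need at least 4 observations")
  if (length(unique(df$season)) < 3) {
    abort("subjects must span at least 3 distinct seasons (design is rank-deficient)")
  }
  w <- season_omega()
  df$t <- season_code(df$season)
  df$sin_t <- sin(w * df$t)
  df$cos_t <- cos(w * df$t)
  fit <- lm(value ~ sin_t + cos_t, data = df)

  cf <- coef(fit)
  a <- unname(cf["sin_t"])
  b <- unname(cf["cos_t"])
  c0 <- unname(cf["(Intercept)"])
  amplitude <- sqrt(a^2 + b^2)
  phase <- if (amplitude > 0) wrap_angle(atan2(-a, b)) else 0

  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((df$value - mean(df$value))^2)
  df2 <- n - 3L
  f_stat <- if (rss == 0 && tss == 0) 0 else ((tss - rss) / 2) / (rss / df2)
  p_value <- pf(f_stat, 2, df2, lower.tail = FALSE)
  r2 <- if (tss == 0) 0 else 1 - rss / tss

  t_grid <- seq(0, 4, length.out = band_points + 1L)[seq_len(band_points)]
  band <- as.data.frame(predict(
    fit,
    newdata = data.frame(sin_t = sin(w * t_grid), cos_t = cos(w * t_grid)),
    interval = "confidence", level = 0.95
  ))
  band <- tibble::tibble(t = t_grid, fit = band$fit,
                         lwr = band$lwr, upr = band$upr)

  fitted_at <- c0 + a * sin(w * 0:3) + b * cos(w * 0:3)
  structure(
    list(
      a = a, b = b, c = c0,
      amplitude = amplitude, phase = phase,
      f_statistic = f_stat, df1 = 2L, df2 = df2, p_value = p_value,
      r_squared = r2, cohens_f = sqrt(r2 / max(1 - r2, .Machine$double.eps)),
      n = n,
      band = band,
      fitted_by_season = tibble::tibble(
        season = factor(season_levels(), levels = season_levels()),
        t = 0:3, fit = fitted_at
      ),
      peak_season = season_levels()[which.max(fitted_at)],
      groups = season_group_summary(df, value, season),
      model = fit
    ),
    class = "seasonal_fit"
  )
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat("Cosinor fit (period 4 quarters)\n")
  cat(sprintf(
    "  amplitude A = %.4f, phase = %.4f rad (peak: %s), mesor c = %.4f\n",
    x$amplitude, x$phase, x$peak_season, x$c
  ))
  cat(sprintf(
    "  periodicity F(%d, %d) = %.4f, p = %.4g, Cohen's f = %.4f (n = %d)\n",
    x$df1, x$df2, x$f_statistic, x$p_value, x$cohens_f, x$n
  ))
  invisible(x)
}

#' Regression of a measure on environmental covariates
#'
#' Replaces the sinusoidal regressors by measured environmental factors:
#' each subject's adjusted measure is regressed on the mean temperature and
#' mean daylength of its acquisition season-year (optionally lagged by whole
#' quarters). Per-coefficient t-tests, the overall F-test and Cohen's f
#' (`sqrt(R^2 / (1 - R^2))`) are reported.
#'
#' @inheritParams season_group_summary
#' @param year Unquoted name of the cohort-year column.
#' @param env Environment table as from [generate_environment()] (columns
#'   `season`, `year`, `mean_temperature`, `mean_daylength`).
#' @param lag_quarters Integer: use the environment of this many quarters
#'   before the acquisition quarter (default 0).
#' @param condition_max Condition-number guard on the scaled design; beyond
#'   it the temperature/daylength design is declared collinear.
#'
#' @return An object of class `env_regression` with `tidy()` and `glance()`
#'   methods.
#' @export
environmental_regression <- function(data, value, env,
                                     season = season, year = year,
                                     lag_quarters = 0L,
                                     condition_max = 1e8) {
  df <- seasonal_frame(data, {{ value }}, {{ season }})
  df$year <- as.integer(dplyr::pull(data, {{ year }}))
  lag_quarters <- assert_count(lag_quarters, "lag_quarters")
  if (!all(c("season", "year", "mean_temperature", "mean_daylength")
           %in% names(env))) {
    abort("`env` needs columns season, year, mean_temperature, mean_daylength")
  }

  # shift each subject's quarter index back by the lag
  q <- df$year * 4L + season_code(df$season) - lag_quarters
  df$env_year <- q %/% 4L
  df$env_season <- season_levels()[q %% 4L + 1L]

  env2 <- tibble::tibble(
    env_season = as.character(env$season),
    env_year = as.integer(env$year),
    temperature = env$mean_temperature,
    daylength = env$mean_daylength
  )
  joined <- dplyr::left_join(df, env2, by = c("env_season", "env_year"))
  if (anyNA(joined$temperature) || anyNA(joined$daylength)) {
    miss <- unique(paste0(joined$env_season, "-", joined$env_year)[
      is.na(joined$temperature)
    ])
    abort(paste0("environment table is missing season-year(s): ",
                 paste(miss, collapse = ", ")))
  }

  X <- cbind(joined$temperature, joined$daylength)
  if (any(apply(X, 2, sd) == 0) ||
      kappa(scale(X), exact = TRUE) > condition_max) {
    abort(paste0(
      "temperature and daylength are (near-)collinear across the design ",
      "(condition-number guard); the regression is not identifiable"
    ))
  }
  fit <- lm(value ~ temperature + daylength, data = joined)
  sm <- summary(fit)
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    std_error = sm$coefficients[, 2],
    statistic = sm$coefficients[, 3],
    p_value = sm$coefficients[, 4]
  )
  r2 <- sm$r.squared
  structure(
    list(
      coefficients = coefs,
      f_statistic = unname(sm$fstatistic[1]),
      df1 = unname(sm$fstatistic[2]),
      df2 = unname(sm$fstatistic[3]),
      p_value = pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                   lower.tail = FALSE),
      r_squared = r2,
      cohens_f = sqrt(r2 / max(1 - r2, .Machine$double.eps)),
      n = nrow(joined),
      lag_quarters = lag_quarters,
      model = fit
    ),
    class = "env_regression"
  )
}

#' @export
print.env_regression <- function(x, ...) {
  cat(sprintf(
    "Environmental regression (lag %d quarters): F(%g, %g) = %.4f, p = %.4g, Cohen's f = %.4f\n",
    x$lag_quarters, x$df1, x$df2, x$f_statistic, x$p_value, x$cohens_f
  ))
  print(x$coefficients)
  invisible(x)
}
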