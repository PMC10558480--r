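#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.seasonal_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  terms <- c("(Intercept)" = "mesor", "sin_t" = "sin", "cos_t" = "cos")
  tibble::tibble(
    term = unname(terms[rownames(sm)]),
    estimate = sm[, 1],
    std_error = sm[, 2],
    statistic = sm[, 3],
    p_value = sm[, 4]
  )
}

#' @export
glance.seasonal_fit <- function(x, ...) {
  tibble::tibble(
    amplitude = x$amplitude,
    phase = x$phase,
    mesor = x$c,
    peak_season = x$peak_season,
    f_statistic = x$f_statistic,
    df1 = x$df1,
    df2 = x$df2,
    p_value = x$p_value,
    r_squared = x$r_squared,
    cohens_f = x$cohens_f,
    n = x$n
  )
}

#' @export
tidy.season_anova <- function(x, ...) x$groups

#' @export
glance.season_anova <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic,
    df1 = x$df1,
    df2 = x$df2,
    p_value = x$p_value,
    eta_squared = x$eta_squared,
    cohens_f = x$cohens_f,
    n = x$n
  )
}

#' @export
tidy.env_regression <- function(x, ...) x$coefficients

#' @export
glance.env_regression <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic,
    df1 = x$df1,
    df2 = x$df2,
    p_value = x$p_value,
    r_squared = x$r_squared,
    cohens_f = x$cohens_f,
    temperature_p = x$coefficients$p_value[x$coefficients$term == "temperature"],
    daylength_p = x$coefficients$p_value[x$coefficients$term == "daylength"],
    lag_quarters = x$lag_quarters,
    n = x$n
  )
}
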