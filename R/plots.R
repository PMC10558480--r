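#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cosinor fit over the season-group means
#'
#' Group means with standard-error bars, overlaid with the continuous fitted
#' sinusoid and its 95 percent pointwise confidence band — the conventional
#' display for a seasonal-periodicity fit.
#'
#' @param object A `seasonal_fit` from [fit_seasonal_sinusoid()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.seasonal_fit <- function(object, ...) {
  groups <- dplyr::mutate(object$groups, t = season_code(.data$season))
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = object$band,
      ggplot2::aes(x = .data$t, ymin = .data$lwr, ymax = .data$upr),
      fill = "darkorange", alpha = 0.3
    ) +
    ggplot2::geom_line(
      data = object$band,
      ggplot2::aes(x = .data$t, y = .data$fit),
      color = "red", linewidth = 0.8
    ) +
    ggplot2::geom_errorbar(
      data = groups,
      ggplot2::aes(x = .data$t,
                   ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.1, color = "steelblue"
    ) +
    ggplot2::geom_point(
      data = groups,
      ggplot2::aes(x = .data$t, y = .data$mean),
      color = "steelblue", size = 2
    ) +
    ggplot2::scale_x_continuous(
      breaks = 0:3, labels = season_levels(), limits = c(-0.2, 3.6)
    ) +
    ggplot2::labs(
      x = NULL, y = "measure",
      subtitle = sprintf("A = %.3g, phase = %.3g rad, F(%d, %d) = %.3g, p = %.3g",
                         object$amplitude, object$phase, object$df1,
                         object$df2, object$f_statistic, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot group mean power spectra by season
#'
#' @param spectra A tibble with columns `frequency_hz`, `power` and `season`
#'   (e.g. several [group_mean_spectrum()] outputs bound together with a
#'   season column).
#' @param band Low-frequency band to shade (default 0.01-0.08 Hz).
#'
#' @return A ggplot object.
#' @export
plot_group_spectra <- function(spectra, band = c(0.01, 0.08)) {
  ggplot2::ggplot(
    spectra,
    ggplot2::aes(x = .data$frequency_hz, y = .data$power,
                 color = .data$season)
  ) +
    ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "blue") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power spectral density") +
    ggplot2::theme_minimal()
}

#' Plot the per-measure seasonal summaries of a results bundle
#'
#' One panel per measure: season-group means with SEM bars and the fitted
#' cosinor curve.
#'
#' @param object A `seasonfc_results` from [run_pipeline()].
#' @param measures Optional character vector restricting the panels.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.seasonfc_results <- function(object, measures = NULL, ...) {
  fits <- object$cosinor_fits
  if (!is.null(measures)) fits <- fits[intersect(names(fits), measures)]
  groups <- purrr::imap_dfr(fits, function(f, m) {
    dplyr::mutate(f$groups, measure = m, t = season_code(.data$season))
  })
  bands <- purrr::imap_dfr(fits, function(f, m) {
    dplyr::mutate(f$band, measure = m)
  })
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = bands,
      ggplot2::aes(x = .data$t, ymin = .data$lwr, ymax = .data$upr),
      fill = "darkorange", alpha = 0.3
    ) +
    ggplot2::geom_line(
      data = bands, ggplot2::aes(x = .data$t, y = .data$fit), color = "red"
    ) +
    ggplot2::geom_errorbar(
      data = groups,
      ggplot2::aes(x = .data$t, ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.1, color = "steelblue"
    ) +
    ggplot2::geom_point(
      data = groups, ggplot2::aes(x = .data$t, y = .data$mean),
      color = "steelblue"
    ) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = 0:3, labels = season_levels()) +
    ggplot2::labs(x = NULL, y = "adjusted measure") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
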