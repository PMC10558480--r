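#' Welch estimator parameters
#'
#' Defaults follow the conventional averaged-periodogram setup: the signal is
#' divided into 8 segments with 50 percent overlap and a Hamming taper — the
#' defaults of the MATLAB `pwelch` routine.
#'
#' @param n_segments Number of segments the signal is divided into.
#' @param overlap_fraction Fractional overlap between consecutive segments,
#'   in `[0, 1)`.
#' @param window Taper name: `"hamming"`, `"hann"` or `"rectangular"`.
#'
#' @return A `welch_params` list.
#' @export
welch_params <- function(n_segments = 8L, overlap_fraction = 0.5,
                         window = c("hamming", "hann", "rectangular")) {
  n_segments <- assert_count(n_segments, "n_segments", min = 1L)
  assert_scalar_number(overlap_fraction, "overlap_fraction")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must be in [0, 1)")
  }
  window <- match.arg(window)
  structure(
    list(
      n_segments = n_segments,
      overlap_fraction = overlap_fraction,
      window = window
    ),
    class = "welch_params"
  )
}

taper_window <- function(name, L) {
  k <- seq_len(L) - 1
  switch(name,
    hamming = 0.54 - 0.46 * cos(2 * pi * k / (L - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * k / (L - 1)),
    rectangular = rep(1, L),
    abort(paste0("unknown window: ", name))
  )
}

#' Welch power spectral density of a single time series
#'
#' Averaged modified periodogram over overlapping tapered segments, with
#' one-sided density scaling: for a zero-mean signal,
#' `sum(power) * delta_f` approximates the signal variance (Parseval).
#'
#' @param x Numeric vector (a single region's time series).
#' @param tr_seconds Sampling interval in seconds.
#' @param params A [welch_params()] object.
#'
#' @return A tibble with columns `frequency_hz` (ascending, 0 to Nyquist) and
#'   `power` (nonnegative), with the bin width in attribute `"delta_f"`.
#' @export
#' @examples
#' t <- seq(0, by = 0.72, length.out = 1200)
#' psd <- welch_psd(sin(2 * pi * 0.05 * t), tr_seconds = 0.72)
#' psd$frequency_hz[which.max(psd$power)]
welch_psd <- function(x, tr_seconds, params = welch_params()) {
  if (!is.numeric(x) || anyNA(x)) abort("`x` must be a numeric vector without NAs")
  assert_scalar_number(tr_seconds, "tr_seconds")
  if (tr_seconds <= 0) abort("`tr_seconds` must be positive")
  if (!inherits(params, "welch_params")) params <- do.call(welch_params, params)

  n <- length(x)
  fs <- 1 / tr_seconds
  # segment length such that n_segments segments at the given overlap tile x
  L <- floor(n / ((params$n_segments - 1) * (1 - params$overlap_fraction) + 1))
  if (L < 8) {
    abort(sprintf(
      "signal too short: segment length %d < 8 samples (n = %d, %d segments)",
      L, n, params$n_segments
    ))
  }
  step <- max(1L, L - floor(params$overlap_fraction * L))
  starts <- seq(1L, n - L + 1L, by = step)

  w <- taper_window(params$window, L)
  scale <- fs * sum(w^2)
  n_keep <- floor(L / 2) + 1L

  acc <- numeric(n_keep)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    p <- abs(fft(seg))^2 / scale
    acc <- acc + p[seq_len(n_keep)]
  }
  pxx <- acc / length(starts)
  # one-sided: double every bin that has a conjugate twin
  dbl <- 2:(if (L %% 2 == 0) n_keep - 1L else n_keep)
  pxx[dbl] <- 2 * pxx[dbl]

  out <- tibble::tibble(
    frequency_hz = (seq_len(n_keep) - 1) * fs / L,
    power = pxx
  )
  attr(out, "delta_f") <- fs / L
  attr(out, "params") <- params
  out
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' The ratio of the power summed over the low-frequency band (0.01-0.08 Hz by
#' default, band edges included) to the power summed over all frequencies
#' strictly above `denom_low`. For a spectrum concentrated inside the band the
#' ratio is 1; for power entirely above the band it is 0.
#'
#' @param spectrum A spectrum as returned by [welch_psd()] (columns
#'   `frequency_hz` and `power`), or any data frame with those columns.
#' @param band_low,band_high Numerator band edges in Hz (inclusive).
#' @param denom_low Denominator lower edge in Hz (exclusive).
#'
#' @return A scalar in `[0, 1]`.
#' @export
falff <- function(spectrum, band_low = 0.01, band_high = 0.08,
                  denom_low = 0.01) {
  if (!all(c("frequency_hz", "power") %in% names(spectrum))) {
    abort("`spectrum` needs columns `frequency_hz` and `power`")
  }
  f <- spectrum$frequency_hz
  p <- spectrum$power
  if (any(p < 0) || anyNA(p)) abort("power must be nonnegative and finite")
  if (is.unsorted(f, strictly = TRUE)) abort("frequency grid must be strictly ascending")
  num <- sum(p[f >= band_low & f <= band_high])
  den <- sum(p[f > denom_low])
  if (den <= 0) abort("zero power above `denom_low`: fALFF undefined")
  num / den
}

#' Per-region fALFF for one subject's time series
#'
#' Signals are normalized to unit variance but deliberately NOT band-pass
#' filtered before spectral estimation, so the full spectrum enters the fALFF
#' denominator.
#'
#' @param x Timepoints x regions matrix (raw, unfiltered).
#' @inheritParams welch_psd
#' @inheritParams falff
#'
#' @return A tibble with columns `region` and `falff`.
#' @export
region_falff <- function(x, tr_seconds, params = welch_params(),
                         band_low = 0.01, band_high = 0.08,
                         denom_low = 0.01) {
  x <- normalize_unit_variance(x)
  labels <- colnames(x) %||% sprintf("region%03d", seq_len(ncol(x)))
  vals <- vapply(seq_len(ncol(x)), function(j) {
    falff(welch_psd(x[, j], tr_seconds, params),
          band_low = band_low, band_high = band_high, denom_low = denom_low)
  }, numeric(1))
  tibble::tibble(region = labels, falff = vals)
}

#' Mean fALFF over the regions of one tissue class
#'
#' @param falff_table A per-region fALFF table (columns `region`, `falff`) as
#'   returned by [region_falff()].
#' @param regions Region metadata (columns `region`, `tissue`).
#' @param tissue `"GM"` or `"WM"`.
#'
#' @return A scalar: the unweighted mean fALFF over regions of that tissue.
#' @export
mean_tissue_falff <- function(falff_table, regions, tissue = c("GM", "WM")) {
  tissue <- match.arg(tissue)
  keep <- regions$region[regions$tissue == tissue]
  vals <- falff_table$falff[falff_table$region %in% keep]
  if (length(vals) == 0) {
    abort(paste0("no regions of tissue ", tissue, " in the fALFF table"))
  }
  mean(vals)
}

#' Per-subject mean GM and WM fALFF for a cohort
#'
#' @param cohort An `fc_cohort`.
#' @inheritParams region_falff
#'
#' @return A tibble with one row per subject: `id`, `sex`, `season`, `year`,
#'   `falff_gm`, `falff_wm`.
#' @export
cohort_falff <- function(cohort, params = welch_params(),
                         band_low = 0.01, band_high = 0.08,
                         denom_low = 0.01) {
  stopifnot(inherits(cohort, "fc_cohort"))
  rows <- purrr::map(cohort$subjects$id, function(id) {
    tab <- region_falff(
      cohort$series[[id]], cohort$tr_seconds, params,
      band_low = band_low, band_high = band_high, denom_low = denom_low
    )
    tibble::tibble(
      id = id,
      falff_gm = mean_tissue_falff(tab, cohort$regions, "GM"),
      falff_wm = mean_tissue_falff(tab, cohort$regions, "WM")
    )
  })
  dplyr::left_join(cohort$subjects, dplyr::bind_rows(rows), by = "id")
}

#' Season-group mean power spectrum for one tissue class
#'
#' Per-region spectra (on normalized, unfiltered signals) are averaged over
#' the regions of the tissue within each subject, then over the subjects of
#' the season group.
#'
#' @inheritParams cohort_falff
#' @param season Season name of the group.
#' @param tissue `"GM"` or `"WM"`.
#'
#' @return A spectrum tibble (`frequency_hz`, `power`) with attribute
#'   `"n_subjects"`.
#' @export
group_mean_spectrum <- function(cohort, season, tissue = c("GM", "WM"),
                                params = welch_params()) {
  stopifnot(inherits(cohort, "fc_cohort"))
  tissue <- match.arg(tissue)
  season <- match.arg(season, season_levels())
  ids <- cohort$subjects$id[cohort$subjects$season == season]
  if (length(ids) == 0) abort(paste0("no subjects in season ", season))
  keep <- cohort$regions$region[cohort$regions$tissue == tissue]
  if (length(keep) == 0) abort(paste0("no regions of tissue ", tissue))

  per_subject <- purrr::map(ids, function(id) {
    x <- normalize_unit_variance(cohort$series[[id]][, keep, drop = FALSE])
    specs <- lapply(seq_len(ncol(x)), function(j) {
      welch_psd(x[, j], cohort$tr_seconds, params)
    })
    pow <- rowMeans(vapply(specs, `[[`, numeric(nrow(specs[[1]])), "power"))
    list(frequency_hz = specs[[1]]$frequency_hz, power = pow)
  })
  freq <- per_subject[[1]]$frequency_hz
  pow <- rowMeans(vapply(per_subject, `[[`, numeric(length(freq)), "power"))
  out <- tibble::tibble(frequency_hz = freq, power = pow)
  attr(out, "n_subjects") <- length(ids)
  out
}
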