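#' Band-pass filter region-averaged BOLD signals
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass filter to
#' every column of a timepoints x regions matrix. The default band 0.01-0.1 Hz
#' retains the low-frequency fluctuations conventionally analysed in
#' resting-state functional connectivity. Zero-phase filtering is used so that
#' no phase shift distorts inter-regional correlation structure.
#'
#' @param x Numeric matrix, timepoints in rows, regions in columns.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 * tr_seconds)`.
#' @param order Butterworth section order; the band-pass filter has twice this
#'   order (default 2, i.e. a 4th-order band-pass), applied forward and
#'   backward.
#'
#' @return A matrix of the same dimensions and dimnames as `x`.
#' @export
#' @examples
#' x <- matrix(rnorm(400), 200, 2)
#' xf <- bandpass_filter(x, tr_seconds = 0.72)
bandpass_filter <- function(x, tr_seconds, low_hz = 0.01, high_hz = 0.1,
                            order = 2) {
  x <- as_timeseries_matrix(x)
  assert_scalar_number(tr_seconds, "tr_seconds")
  if (tr_seconds <= 0) abort("`tr_seconds` must be positive")
  nyquist <- 1 / (2 * tr_seconds)
  assert_scalar_number(low_hz, "low_hz")
  assert_scalar_number(high_hz, "high_hz")
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyquist)) {
    abort(sprintf(
      "band edges must satisfy 0 < low_hz < high_hz < Nyquist (%.4f Hz)",
      nyquist
    ))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  dimnames(out) <- dimnames(x)
  out
}

#' Normalize each region's signal to zero mean and unit variance
#'
#' Columns are centred and scaled to unit sample variance. Centring is
#' included because downstream Pearson correlation assumes it and it leaves
#' variance-based measures untouched.
#'
#' @inheritParams bandpass_filter
#'
#' @return Matrix of the same dimensions with column sample variance 1.
#' @export
normalize_unit_variance <- function(x) {
  x <- as_timeseries_matrix(x)
  s <- apply(x, 2, sd)
  if (any(s == 0 | !is.finite(s))) {
    bad <- colnames(x)[s == 0 | !is.finite(s)]
    if (is.null(bad)) bad <- which(s == 0 | !is.finite(s))
    abort(paste0(
      "cannot normalize constant/non-finite region(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  out <- scale(x, center = TRUE, scale = s)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  dimnames(out) <- dimnames(x)
  out
}

#' Average voxel time series into region time series
#'
#' @param voxel_series Numeric matrix, timepoints x voxels.
#' @param membership Character/factor vector, one region label per voxel.
#' @param regions Optional character vector giving the regions expected and
#'   their output order; every listed region must have at least one voxel.
#'
#' @return Matrix timepoints x regions whose columns are unweighted means of
#'   the member voxel columns.
#' @export
region_average <- function(voxel_series, membership, regions = NULL) {
  voxel_series <- as_timeseries_matrix(voxel_series)
  membership <- as.character(membership)
  if (length(membership) != ncol(voxel_series)) {
    abort("`membership` must have one label per voxel column")
  }
  if (anyNA(membership)) abort("`membership` contains missing labels")
  if (is.null(regions)) {
    regions <- unique(membership)
  } else {
    unknown <- setdiff(membership, regions)
    if (length(unknown) > 0) {
      abort(paste0("unknown region label(s): ", paste(unknown, collapse = ", ")))
    }
    empty <- setdiff(regions, membership)
    if (length(empty) > 0) {
      abort(paste0("region(s) with no voxels: ", paste(empty, collapse = ", ")))
    }
  }
  out <- vapply(
    regions,
    function(r) rowMeans(voxel_series[, membership == r, drop = FALSE]),
    numeric(nrow(voxel_series))
  )
  colnames(out) <- regions
  out
}

#' Region-average a 4D BOLD NIfTI volume with an integer-label atlas
#'
#' Convenience wrapper around [region_average()] for NIfTI inputs. Voxels with
#' atlas label 0 are treated as background and dropped.
#'
#' @param bold_file Path to a 4D BOLD NIfTI file.
#' @param atlas_file Path to a 3D integer-label NIfTI atlas in the same grid.
#' @param labels Optional named integer vector mapping region names to atlas
#'   integer codes; defaults to `region_<code>` for every nonzero code.
#'
#' @return Matrix timepoints x regions.
#' @export
region_average_nifti <- function(bold_file, atlas_file, labels = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("the RNifti package is required for NIfTI input")
  }
  bold <- RNifti::readNifti(bold_file)
  atlas <- RNifti::readNifti(atlas_file)
  dm <- dim(bold)
  if (length(dm) != 4) abort("`bold_file` must be a 4D volume")
  if (!identical(dim(atlas)[1:3], dm[1:3])) {
    abort("atlas grid does not match the BOLD volume")
  }
  codes <- as.integer(atlas)
  keep <- which(codes != 0L)
  mat <- t(matrix(bold, prod(dm[1:3]), dm[4])[keep, , drop = FALSE])
  if (is.null(labels)) {
    codes_present <- sort(unique(codes[keep]))
    labels <- setNames(codes_present, sprintf("region_%d", codes_present))
  }
  membership <- names(labels)[match(codes[keep], labels)]
  region_average(mat, membership, regions = names(labels))
}

#' Regress a nuisance covariate out of a per-subject measure
#'
#' Residualizes `values` on `[covariate, intercept]` by ordinary least squares
#' and adds the grand mean back, so the adjusted measure keeps its original
#' scale but is orthogonal to the centred covariate. This is the standard way
#' to control a nuisance variable (e.g. sex) in derived imaging measures.
#'
#' @param values Numeric vector of per-subject measures.
#' @param covariate Numeric, logical or two-level factor/character vector of
#'   the same length; must not be constant.
#'
#' @return Numeric vector of adjusted measures with `mean(adjusted) ==
#'   mean(values)`.
#' @export
residualize_on_covariate <- function(values, covariate) {
  if (!is.numeric(values)) abort("`values` must be numeric")
  cov_num <- covariate_to_numeric(covariate)
  if (length(values) != length(cov_num)) {
    abort("`values` and `covariate` must have the same length")
  }
  if (anyNA(values) || anyNA(cov_num)) abort("missing values are not allowed")
  if (sd(cov_num) == 0) abort("`covariate` is constant; nothing to regress out")
  fit <- lm(values ~ cov_num)
  unname(stats::residuals(fit)) + mean(values)
}

covariate_to_numeric <- function(covariate) {
  if (is.numeric(covariate)) return(covariate)
  if (is.logical(covariate)) return(as.numeric(covariate))
  f <- as.factor(covariate)
  as.numeric(f) - 1
}

#' Residualize measure columns of a data frame on a covariate
#'
#' Data-frame-first wrapper around [residualize_on_covariate()]: each listed
#' measure column is replaced by its covariate-adjusted version.
#'
#' @param data A data frame with one row per subject.
#' @param measures Character vector of numeric column names to adjust.
#' @param covariate Name of the covariate column (e.g. `"sex"`).
#'
#' @return `data` as a tibble with the measure columns adjusted.
#' @export
residualize_measures <- function(data, measures, covariate = "sex") {
  data <- tibble::as_tibble(data)
  if (!covariate %in% names(data)) {
    abort(paste0("covariate column `", covariate, "` not found"))
  }
  missing_cols <- setdiff(measures, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("measure column(s) not found: ", paste(missing_cols, collapse = ", ")))
  }
  cov <- data[[covariate]]
  for (m in measures) {
    data[[m]] <- residualize_on_covariate(data[[m]], cov)
  }
  data
}

as_timeseries_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expected a numeric timepoints x regions matrix")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("time-series matrix contains non-finite values")
  }
  x
}
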