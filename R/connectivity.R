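#' Pearson functional-connectivity matrix between two region sets
#'
#' Element (i, j) is the sample Pearson correlation between region i of
#' `series_a` and region j of `series_b`. With `series_b = NULL` the
#' within-set matrix is returned (symmetric, unit diagonal). Inputs are
#' expected to be band-pass filtered and normalized, but any finite,
#' non-constant columns are accepted.
#'
#' @param series_a,series_b Timepoints x regions matrices with the same
#'   number of rows; column names label the regions.
#'
#' @return A correlation matrix with row/column dimnames taken from the
#'   inputs.
#' @export
pearson_fc <- function(series_a, series_b = NULL) {
  series_a <- as_timeseries_matrix(series_a)
  check_nonconstant(series_a, "series_a")
  if (is.null(series_b)) {
    return(cor(series_a))
  }
  series_b <- as_timeseries_matrix(series_b)
  check_nonconstant(series_b, "series_b")
  if (nrow(series_a) != nrow(series_b)) {
    abort("`series_a` and `series_b` must have equal timepoint counts")
  }
  cor(series_a, series_b)
}

check_nonconstant <- function(x, name) {
  s <- apply(x, 2, sd)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0] %||% which(s == 0)
    abort(paste0("constant region(s) in `", name, "`: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' Fisher Z-transform of a correlation matrix
#'
#' Element-wise `atanh(r)`. Correlations with `|r|` at or above the clip
#' bound (unit diagonals, duplicated regions) are clipped to `1 - 1e-7` so
#' the transform stays finite; a warning reports how many elements were
#' clipped.
#'
#' @param fc A correlation matrix (values in `[-1, 1]`).
#' @param clip Magnitude bound applied before `atanh`.
#'
#' @return A matrix of Fisher Z values with the same dimnames.
#' @export
fisher_z <- function(fc, clip = 1 - 1e-7) {
  if (!is.matrix(fc) || !is.numeric(fc)) abort("`fc` must be a numeric matrix")
  if (any(!is.finite(fc)) || any(abs(fc) > 1 + 1e-12)) {
    abort("`fc` must contain finite correlations in [-1, 1]")
  }
  over <- abs(fc) > clip
  if (nrow(fc) == ncol(fc)) {
    # a unit self-correlation diagonal is expected; clip it silently
    d <- row(fc) == col(fc) & abs(abs(fc) - 1) < 1e-12
    over <- over & !d
  }
  if (any(over)) {
    warn(sprintf("fisher_z: clipped %d element(s) with |r| > %.7f",
                 sum(over), clip))
  }
  out <- atanh(pmin(pmax(fc, -clip), clip))
  dimnames(out) <- dimnames(fc)
  out
}

#' Mean absolute Fisher Z over a connectivity matrix
#'
#' The scalar connectivity-strength summary: the average of `|Z|` over the
#' matrix elements. For a square symmetric within-tissue matrix the unit
#' diagonal and the duplicate lower triangle are excluded by default (each
#' region pair counts once); cross-tissue rectangular matrices use all
#' elements.
#'
#' @param z A Fisher Z matrix from [fisher_z()].
#' @param exclude_diagonal `NULL` (auto: exclude for square symmetric
#'   matrices) or a logical.
#'
#' @return A nonnegative scalar.
#' @export
mean_abs_z <- function(z, exclude_diagonal = NULL) {
  if (!is.matrix(z) || !is.numeric(z)) abort("`z` must be a numeric matrix")
  symmetric <- nrow(z) == ncol(z) && max(abs(z - t(z))) < 1e-10
  if (is.null(exclude_diagonal)) exclude_diagonal <- symmetric
  vals <- if (symmetric && exclude_diagonal) {
    z[upper.tri(z)]
  } else if (exclude_diagonal) {
    if (nrow(z) != ncol(z)) {
      abort("`exclude_diagonal = TRUE` requires a square matrix")
    }
    z[row(z) != col(z)]
  } else {
    as.vector(z)
  }
  if (length(vals) == 0) abort("no elements left after exclusion")
  mean(abs(vals))
}

#' Per-network mean connectivity of a WM x GM Fisher Z matrix
#'
#' The GM columns are partitioned by functional network and the mean of `|Z|`
#' is computed over each WM-rows x network-columns submatrix.
#'
#' @param z Fisher Z matrix with WM bundles as rows and GM regions as
#'   columns (column names required).
#' @param network_map Data frame with columns `region` and `network` mapping
#'   every GM column to exactly one network, or a named character vector.
#'
#' @return A tibble with columns `network`, `n_regions`, `mean_abs_z`,
#'   ordered by network name.
#' @export
network_mean_fc <- function(z, network_map) {
  if (!is.matrix(z) || is.null(colnames(z))) {
    abort("`z` must be a matrix with GM region column names")
  }
  map <- if (is.data.frame(network_map)) {
    setNames(as.character(network_map$network), network_map$region)
  } else {
    network_map
  }
  nets <- map[colnames(z)]
  if (anyNA(nets)) {
    bad <- colnames(z)[is.na(nets)]
    abort(paste0("GM region(s) without a network: ", paste(bad, collapse = ", ")))
  }
  out <- purrr::map_dfr(sort(unique(unname(nets))), function(nw) {
    cols <- which(nets == nw)
    tibble::tibble(
      network = nw,
      n_regions = length(cols),
      mean_abs_z = mean(abs(z[, cols, drop = FALSE]))
    )
  })
  out
}

#' WM-averaged connectivity per GM region
#'
#' For each GM column the mean of `|Z|` over all WM rows — a tabular
#' per-region summary of how strongly each GM region couples to white matter
#' overall.
#'
#' @inheritParams network_mean_fc
#'
#' @return A tibble with columns `region` and `mean_abs_z`.
#' @export
wm_averaged_fc_per_gm <- function(z) {
  if (!is.matrix(z) || !is.numeric(z) || length(z) == 0) {
    abort("`z` must be a nonempty numeric matrix")
  }
  tibble::tibble(
    region = colnames(z) %||% sprintf("region%03d", seq_len(ncol(z))),
    mean_abs_z = unname(colMeans(abs(z)))
  )
}

# filtered + normalized series split by tissue for one subject
subject_tissue_series <- function(cohort, id, low_hz = 0.01, high_hz = 0.1) {
  x <- cohort$series[[id]]
  if (is.null(x)) abort(paste0("unknown subject id: ", id))
  x <- normalize_unit_variance(bandpass_filter(x, cohort$tr_seconds,
                                               low_hz, high_hz))
  gm <- cohort$regions$region[cohort$regions$tissue == "GM"]
  wm <- cohort$regions$region[cohort$regions$tissue == "WM"]
  list(gm = x[, gm, drop = FALSE], wm = x[, wm, drop = FALSE], all = x)
}

#' Per-subject connectivity summaries for a cohort
#'
#' For every subject: band-pass filter (default 0.01-0.1 Hz) and normalize
#' the signals, form the WM x GM, GM x GM and WM x WM Pearson matrices,
#' Fisher Z-transform them, and summarize each as a mean `|Z|`. Per-network
#' and per-GM-region (WM-averaged) summaries are returned alongside.
#'
#' @param cohort An `fc_cohort`.
#' @param low_hz,high_hz Band edges for the connectivity preprocessing.
#' @param summaries Which summary levels to compute: subset of
#'   `c("global", "network", "per_gm_region")`.
#'
#' @return A list of tibbles: `global` (one row per subject: `z_gm_wm`,
#'   `z_gm_gm`, `z_wm_wm`), `network` (subject x network mean `|Z|`, long),
#'   and `per_gm_region` (subject x GM region WM-averaged `|Z|`, long);
#'   levels not requested are `NULL`.
#' @export
cohort_connectivity <- function(cohort, low_hz = 0.01, high_hz = 0.1,
                                summaries = c("global", "network",
                                              "per_gm_region")) {
  stopifnot(inherits(cohort, "fc_cohort"))
  summaries <- match.arg(summaries, several.ok = TRUE)
  gm_map <- cohort$regions[cohort$regions$tissue == "GM", c("region", "network")]
  have_networks <- "network" %in% summaries && !anyNA(gm_map$network)
  nets <- if (have_networks) sort(unique(gm_map$network))
  want_per_gm <- "per_gm_region" %in% summaries

  ids <- cohort$subjects$id
  n <- length(ids)
  glob <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("z_gm_wm", "z_gm_gm", "z_wm_wm")))
  net_mat <- if (have_networks) {
    matrix(NA_real_, n, length(nets), dimnames = list(NULL, nets))
  }
  gm_regions <- gm_map$region
  per_gm_mat <- if (want_per_gm) {
    matrix(NA_real_, n, length(gm_regions), dimnames = list(NULL, gm_regions))
  }
  net_cols <- if (have_networks) {
    lapply(nets, function(nw) which(gm_map$network == nw))
  }

  for (i in seq_len(n)) {
    ts <- subject_tissue_series(cohort, ids[i], low_hz, high_hz)
    z_cross <- fisher_z(pearson_fc(ts$wm, ts$gm))
    glob[i, 1] <- mean(abs(z_cross))
    glob[i, 2] <- mean_abs_z(fisher_z(pearson_fc(ts$gm)))
    glob[i, 3] <- mean_abs_z(fisher_z(pearson_fc(ts$wm)))
    if (have_networks) {
      az <- abs(z_cross)
      net_mat[i, ] <- vapply(net_cols, function(cols) {
        mean(az[, cols, drop = FALSE])
      }, numeric(1))
    }
    if (want_per_gm) per_gm_mat[i, ] <- colMeans(abs(z_cross))
  }

  meta <- cohort$subjects
  to_long <- function(mat, key) {
    wide <- dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(mat))
    long <- tidyr::pivot_longer(wide, -"id", names_to = key,
                                values_to = "mean_abs_z")
    dplyr::left_join(long, meta, by = "id")
  }
  list(
    global = if ("global" %in% summaries) {
      dplyr::left_join(meta,
                       dplyr::bind_cols(tibble::tibble(id = ids),
                                        tibble::as_tibble(glob)),
                       by = "id")
    },
    network = if (have_networks) to_long(net_mat, "network"),
    per_gm_region = if (want_per_gm) to_long(per_gm_mat, "region")
  )
}
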