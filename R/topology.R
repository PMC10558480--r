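#' Threshold and binarize a square connectivity matrix
#'
#' Edge (i, j), i != j, exists iff the correlation exceeds `tau` (default
#' 0.2); in `"absolute"` mode the magnitude is compared instead, so strong
#' negative correlations also become edges. The diagonal is forced to zero.
#'
#' @param fc Square symmetric correlation matrix.
#' @param tau Threshold (default 0.2).
#' @param mode `"raw"` (edge iff `r > tau`) or `"absolute"` (edge iff
#'   `|r| > tau`).
#'
#' @return A binary symmetric adjacency matrix with zero diagonal, same
#'   dimnames.
#' @export
threshold_binarize <- function(fc, tau = 0.2, mode = c("raw", "absolute")) {
  mode <- match.arg(mode)
  if (!is.matrix(fc) || !is.numeric(fc) || nrow(fc) != ncol(fc)) {
    abort("`fc` must be a square numeric matrix")
  }
  if (!isTRUE(all.equal(unname(fc), unname(t(fc)), tolerance = 1e-8))) {
    abort("`fc` must be symmetric")
  }
  assert_scalar_number(tau, "tau")
  vals <- if (mode == "absolute") abs(fc) else fc
  adj <- (vals > tau) * 1
  adj[row(adj) == col(adj)] <- 0
  adj <- ((adj + t(adj)) > 0) * 1  # exact symmetry despite float asymmetry
  dimnames(adj) <- dimnames(fc)
  adj
}

check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    abort("adjacency must be a square matrix")
  }
  if (!all(adj %in% c(0, 1))) abort("adjacency entries must be 0/1")
  if (any(diag(adj) != 0)) abort("adjacency diagonal must be zero")
  if (!identical(unname(adj * 1), unname(t(adj) * 1))) {
    abort("adjacency must be symmetric")
  }
  invisible(adj)
}

#' Graph density
#'
#' Fraction of possible undirected connections that are present:
#' `edges / (N (N - 1) / 2)`.
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal.
#'
#' @return Scalar in `[0, 1]`.
#' @export
graph_density <- function(adj) {
  check_adjacency(adj)
  n <- nrow(adj)
  if (n < 2) abort("density needs at least 2 nodes")
  sum(adj) / (n * (n - 1))
}

#' Graph transitivity (global clustering coefficient)
#'
#' Ratio of closed triplets to all connected triplets, computed as
#' `tr(X^3) / (sum(X^2) - tr(X^2))` for the 0/1 connection matrix `X`.
#'
#' @inheritParams graph_density
#' @param zero_denominator What to do when the graph has no path of length
#'   two: `"error"` (default) or `"zero"`.
#'
#' @return Scalar in `[0, 1]`.
#' @export
graph_transitivity <- function(adj, zero_denominator = c("error", "zero")) {
  check_adjacency(adj)
  zero_denominator <- match.arg(zero_denominator)
  x2 <- adj %*% adj
  denom <- sum(x2) - sum(diag(x2))
  if (denom == 0) {
    if (zero_denominator == "zero") return(0)
    abort("no connected triplets: transitivity undefined")
  }
  num <- sum(diag(x2 %*% adj))
  num / denom
}

#' All-pairs unweighted shortest-path lengths
#'
#' Breadth-first search from every node; unreachable pairs get `Inf`, the
#' diagonal 0.
#'
#' @inheritParams graph_density
#'
#' @return N x N numeric matrix of path lengths.
#' @export
shortest_path_matrix <- function(adj) {
  check_adjacency(adj)
  n <- nrow(adj)
  nbrs <- apply(adj > 0, 1, which, simplify = FALSE)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    level <- 0
    while (length(frontier) > 0) {
      level <- level + 1
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- level
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

#' Global efficiency
#'
#' Average inverse shortest-path length over ordered node pairs,
#' `1/(N(N-1)) * sum_{i != j} 1/d_ij`, with unreachable pairs contributing 0.
#'
#' @inheritParams graph_density
#'
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  check_adjacency(adj)
  n <- nrow(adj)
  if (n < 2) abort("global efficiency needs at least 2 nodes")
  d <- shortest_path_matrix(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0  # unreachable pairs
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean shortest-path length over unordered pairs of nodes that are
#' reachable from each other; unreachable pairs are excluded rather than
#' counted as infinite.
#'
#' @inheritParams graph_density
#'
#' @return Scalar `>= 1` whenever any edge exists.
#' @export
characteristic_path_length <- function(adj) {
  check_adjacency(adj)
  d <- shortest_path_matrix(adj)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) abort("no reachable pairs: path length undefined")
  mean(vals)
}

#' The four binary-graph metrics of an adjacency matrix
#'
#' @inheritParams graph_transitivity
#'
#' @return A one-row tibble: `density`, `transitivity`, `global_efficiency`,
#'   `characteristic_path_length`.
#' @export
graph_metrics <- function(adj, zero_denominator = c("error", "zero")) {
  check_adjacency(adj)
  tibble::tibble(
    density = graph_density(adj),
    transitivity = graph_transitivity(adj, zero_denominator),
    global_efficiency = global_efficiency(adj),
    characteristic_path_length = characteristic_path_length(adj)
  )
}

#' Per-subject graph metrics for a cohort
#'
#' For every subject, builds the GM-GM, WM-WM and overall (union of GM and
#' WM regions) Pearson correlation matrices from band-pass filtered,
#' normalized signals, thresholds and binarizes them (raw `r > tau` by
#' default), and computes the four graph metrics.
#'
#' @inheritParams cohort_connectivity
#' @param tau Binarization threshold on the correlation (default 0.2).
#' @param mode Passed to [threshold_binarize()].
#' @param matrix_kinds Subset of `c("gm_gm", "wm_wm", "overall")`.
#' @param zero_denominator Passed to [graph_transitivity()]; the default
#'   `"zero"` keeps degenerate (near-empty) subject graphs in the table.
#'
#' @return A tibble with one row per subject x matrix kind: subject metadata,
#'   `matrix_kind`, and the four metrics.
#' @export
cohort_graph_metrics <- function(cohort, tau = 0.2,
                                 mode = c("raw", "absolute"),
                                 matrix_kinds = c("gm_gm", "wm_wm", "overall"),
                                 low_hz = 0.01, high_hz = 0.1,
                                 zero_denominator = "zero") {
  stopifnot(inherits(cohort, "fc_cohort"))
  mode <- match.arg(mode)
  matrix_kinds <- match.arg(matrix_kinds, several.ok = TRUE)
  rows <- purrr::map(cohort$subjects$id, function(id) {
    ts <- subject_tissue_series(cohort, id, low_hz, high_hz)
    mats <- list(
      gm_gm = if ("gm_gm" %in% matrix_kinds) pearson_fc(ts$gm),
      wm_wm = if ("wm_wm" %in% matrix_kinds) pearson_fc(ts$wm),
      overall = if ("overall" %in% matrix_kinds) pearson_fc(ts$all)
    )
    purrr::imap_dfr(purrr::compact(mats), function(m, kind) {
      adj <- threshold_binarize(m, tau = tau, mode = mode)
      metrics <- if (sum(adj) == 0) {
        tibble::tibble(
          density = 0, transitivity = NA_real_,
          global_efficiency = 0, characteristic_path_length = NA_real_
        )
      } else {
        graph_metrics(adj, zero_denominator = zero_denominator)
      }
      dplyr::mutate(metrics, id = id, matrix_kind = kind, .before = 1)
    })
  })
  dplyr::left_join(dplyr::bind_rows(rows), cohort$subjects, by = "id") |>
    dplyr::relocate("id", "sex", "season", "year")
}
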