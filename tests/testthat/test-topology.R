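test_that("threshold/binarize applies the mode semantics and zeroes the diagonal", {
  fc <- matrix(c(1, 0.1, 0.3, 0.1, 1, -0.5, 0.3, -0.5, 1), 3, 3)
  adj <- threshold_binarize(fc, tau = 0.2)
  expect_equal(adj, matrix(c(0, 0, 1, 0, 0, 0, 1, 0, 0), 3, 3))
  adj_abs <- threshold_binarize(fc, tau = 0.2, mode = "absolute")
  expect_equal(adj_abs[2, 3], 1)  # r = -0.5 becomes an edge in absolute mode
  expect_equal(adj[2, 3], 0)      # but not in raw mode
  expect_true(all(diag(adj_abs) == 0))
  expect_error(threshold_binarize(fc[, 1:2]), "square")
  expect_error(threshold_binarize(matrix(c(0, 1, 0.2, 0), 2, 2)), "symmetric")
})

test_that("graph metrics reproduce hand-computed toy values", {
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(graph_density(k4), 1)
  expect_equal(graph_transitivity(k4), 1)
  expect_equal(global_efficiency(k4), 1)
  expect_equal(characteristic_path_length(k4), 1)

  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- 1
  path4 <- path4 + t(path4)
  expect_equal(graph_density(path4), 0.5)

  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(graph_transitivity(path3), 0)
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(characteristic_path_length(path3), 4 / 3)
  expect_equal(shortest_path_matrix(path3)[1, 3], 2)

  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(graph_transitivity(tri), 1)

  k4_minus <- k4
  k4_minus[1, 2] <- k4_minus[2, 1] <- 0
  expect_equal(graph_transitivity(k4_minus), 0.75)

  # two disjoint K2: unreachable pairs contribute 0 to efficiency and are
  # excluded from the characteristic path length
  two_k2 <- matrix(0, 4, 4)
  two_k2[1, 2] <- two_k2[2, 1] <- two_k2[3, 4] <- two_k2[4, 3] <- 1
  expect_equal(global_efficiency(two_k2), 1 / 3)
  expect_equal(characteristic_path_length(two_k2), 1)
  expect_true(is.infinite(shortest_path_matrix(two_k2)[1, 3]))

  empty <- matrix(0, 3, 3)
  expect_error(characteristic_path_length(empty), "no reachable")
  expect_error(graph_transitivity(empty), "triplets")
  expect_equal(graph_transitivity(empty, zero_denominator = "zero"), 0)
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  ig <- asNamespace("igraph")
  set.seed(51)
  for (r in 1:60) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, sample(c(0.2, 0.5, 0.8), 1))
    g <- ig$graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(graph_density(adj), ig$edge_density(g))
    d_ig <- ig$distances(g)
    expect_equal(shortest_path_matrix(adj), d_ig, ignore_attr = TRUE)
    x2 <- adj %*% adj
    if (sum(x2) - sum(diag(x2)) > 0) {
      expect_equal(graph_transitivity(adj),
                   ig$transitivity(g, type = "global"))
    }
  }
})

test_that("edge additions never decrease density or efficiency", {
  set.seed(52)
  for (r in 1:20) {
    n <- sample(5:10, 1)
    adj <- random_adjacency(n, 0.4)
    off <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (nrow(off) == 0 || sum(adj) == 0) next
    pick <- off[sample(nrow(off), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1
    expect_gt(graph_density(adj2), graph_density(adj))
    expect_gte(global_efficiency(adj2), global_efficiency(adj))
    # path length never increases when the endpoints were already reachable
    d <- shortest_path_matrix(adj)
    if (is.finite(d[pick[1], pick[2]]) && sum(adj) > 0) {
      expect_lte(characteristic_path_length(adj2),
                 characteristic_path_length(adj))
    }
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(53)
  adj <- random_adjacency(9, 0.5)
  m0 <- graph_metrics(adj, zero_denominator = "zero")
  for (r in 1:10) {
    p <- sample(9)
    mp <- graph_metrics(adj[p, p], zero_denominator = "zero")
    expect_equal(mp, m0)
  }
})

test_that("per-subject cohort metrics equal the step-by-step pipeline", {
  co <- make_test_cohort(n_per_season = c(2, 1, 1, 1), n_gm = 4, n_wm = 3,
                         n_networks = 2, n_timepoints = 128, seed = 54)
  out <- cohort_graph_metrics(co, tau = 0.1)
  expect_setequal(unique(out$matrix_kind), c("gm_gm", "wm_wm", "overall"))
  expect_equal(nrow(out), 5 * 3)
  # oracle: redo one subject by hand through the exported primitives
  id <- co$subjects$id[1]
  x <- normalize_unit_variance(
    bandpass_filter(co$series[[id]], co$tr_seconds, 0.01, 0.1)
  )
  fc_all <- pearson_fc(x)
  expected <- graph_metrics(threshold_binarize(fc_all, tau = 0.1),
                            zero_denominator = "zero")
  got <- out[out$id == id & out$matrix_kind == "overall", ]
  expect_equal(got$density, expected$density)
  expect_equal(got$transitivity, expected$transitivity)
  expect_equal(got$global_efficiency, expected$global_efficiency)
  expect_equal(got$characteristic_path_length,
               expected$characteristic_path_length)
  # union matrix embeds the cross-tissue block
  gm <- co$regions$region[co$regions$tissue == "GM"]
  wm <- co$regions$region[co$regions$tissue == "WM"]
  expect_equal(fc_all[wm, gm], pearson_fc(x[, wm], x[, gm]))
})
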