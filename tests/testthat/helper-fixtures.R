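# small cohort factory used across tests
make_test_cohort <- function(n_per_season = c(3, 3, 3, 3),
                             n_gm = 4, n_wm = 3, n_networks = 2,
                             n_timepoints = 128, n_latents = 3,
                             amp = 0, phase = 0, sex_effect = 0,
                             seed = 101) {
  generate_cohort(simulation_config(
    n_per_season = n_per_season,
    n_gm_regions = n_gm, n_wm_regions = n_wm, n_networks = n_networks,
    n_timepoints = n_timepoints, n_latents = n_latents,
    amp_true = amp, phase_true = phase, sex_effect = sex_effect,
    seed = seed
  ))
}

# symmetric 0/1 adjacency of an Erdos-Renyi draw
random_adjacency <- function(n, p) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# ---- independent graph oracles (enumeration / Floyd-Warshall) ----

# transitivity by explicit triplet enumeration over unordered node triples
oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  closed <- 0L
  connected <- 0L
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      e <- adj[i, j] + adj[j, k] + adj[i, k]
      if (e == 3) {
        closed <- closed + 1L
        connected <- connected + 3L # three centred triplets
      } else if (e == 2) {
        connected <- connected + 1L
      }
    }
  }
  if (connected == 0) return(NA_real_)
  (3 * closed) / connected
}

oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# global efficiency with integer-ratio arithmetic: distances on n <= 12
# nodes divide lcm(1..11) = 27720, so the pair sum is an exact integer
oracle_global_efficiency <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  n <- nrow(adj)
  L <- 27720
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) num <- num + L / d[i, j]
  }
  num / (L * n * (n - 1))
}

oracle_char_path_length <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(NA_real_)
  sum(vals) / length(vals)
}

oracle_density <- function(adj) {
  n <- nrow(adj)
  (sum(adj) / 2) / (n * (n - 1) / 2)
}
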