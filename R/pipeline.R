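#' Write a cohort to a directory of delimited text files
#'
#' Layout: `subjects.csv` (id, sex, season, year), `regions.csv` (region,
#' tissue, network), `environment.csv` (optional), one tab-separated
#' time-series file per subject under `series/` (timepoints x regions with a
#' header row of region labels), and a `config.json` sidecar when the cohort
#' carries its generating configuration.
#'
#' @param cohort An `fc_cohort`.
#' @param dir Output directory (created if needed).
#' @param env Optional environment table to write alongside.
#'
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, env = NULL) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(cohort$regions, file.path(dir, "regions.csv"))
  if (!is.null(env)) readr::write_csv(env, file.path(dir, "environment.csv"))
  for (id in cohort$subjects$id) {
    readr::write_tsv(
      tibble::as_tibble(cohort$series[[id]]),
      file.path(dir, "series", paste0(id, ".tsv"))
    )
  }
  meta <- list(tr_seconds = cohort$tr_seconds)
  if (!is.null(cohort$ground_truth)) {
    meta$config <- unclass(cohort$ground_truth)
  }
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cohort from a directory written by [write_cohort()]
#'
#' Validates the tables against each other: unique ids and region labels,
#' tissue in GM/WM, every subject series present with the region columns in
#' table order and a consistent number of timepoints.
#'
#' @param dir Directory containing `subjects.csv`, `regions.csv`,
#'   `config.json` and `series/`.
#' @param require_networks If `TRUE`, every GM region must carry a network
#'   assignment.
#'
#' @return An `fc_cohort` (without simulation ground truth unless the
#'   sidecar carries one).
#' @export
load_cohort <- function(dir, require_networks = FALSE) {
  need <- file.path(dir, c("subjects.csv", "regions.csv", "config.json"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    abort(paste0("missing cohort file(s): ", paste(missing, collapse = ", ")))
  }
  subjects <- readr::read_csv(need[1], show_col_types = FALSE)
  regions <- readr::read_csv(need[2], show_col_types = FALSE)
  meta <- jsonlite::read_json(need[3], simplifyVector = TRUE)
  if (!all(c("id", "sex", "season", "year") %in% names(subjects))) {
    abort("subjects.csv needs columns id, sex, season, year")
  }
  if (!all(c("region", "tissue") %in% names(regions))) {
    abort("regions.csv needs columns region, tissue (and optionally network)")
  }
  if (!"network" %in% names(regions)) regions$network <- NA_character_
  bad_tissue <- setdiff(unique(regions$tissue), c("GM", "WM"))
  if (length(bad_tissue) > 0) {
    abort(paste0("tissue labels outside GM/WM in regions.csv: ",
                 paste(bad_tissue, collapse = ", ")))
  }
  if (require_networks &&
      anyNA(regions$network[regions$tissue == "GM"])) {
    abort("regions.csv: GM region(s) missing a network assignment")
  }
  subjects$season <- factor(subjects$season, levels = season_levels())

  n_time <- NULL
  series <- list()
  for (id in subjects$id) {
    f <- file.path(dir, "series", paste0(id, ".tsv"))
    if (!file.exists(f)) abort(paste0("missing series file: ", f))
    m <- as.matrix(readr::read_tsv(f, show_col_types = FALSE))
    if (!identical(colnames(m), regions$region)) {
      abort(paste0(f, ": columns do not match regions.csv"))
    }
    if (is.null(n_time)) n_time <- nrow(m)
    if (nrow(m) != n_time) {
      abort(sprintf("%s: %d timepoints, expected %d", f, nrow(m), n_time))
    }
    series[[id]] <- m
  }

  gt <- NULL
  if (!is.null(meta$config)) {
    gt <- tryCatch(
      do.call(simulation_config, meta$config[names(meta$config) %in%
        names(formals(simulation_config))]),
      error = function(e) NULL
    )
  }
  new_fc_cohort(subjects, regions, series,
                tr_seconds = meta$tr_seconds, ground_truth = gt)
}

# seasonal statistical battery for one measure column
measure_battery <- function(measures, column, env, alpha) {
  data <- tibble::tibble(
    value = measures[[column]],
    season = measures$season,
    year = measures$year
  )
  an <- anova_seasons(data, value)
  pw <- purrr::map_dfr(
    utils::combn(season_levels(), 2, simplify = FALSE),
    function(p) {
      # degenerate contrasts (e.g. a discrete graph metric constant within
      # both groups of a small cohort) become NA rows instead of aborting
      tryCatch(
        pairwise_seasons(data, value, p[1], p[2]),
        error = function(e) tibble::tibble(
          season_a = p[1], season_b = p[2],
          t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
          cohens_d = NA_real_, mean_diff = NA_real_
        )
      )
    }
  )
  cos_fit <- fit_seasonal_sinusoid(data, value)
  env_fit <- if (!is.null(env)) {
    environmental_regression(data, value, env = env)
  }
  list(anova = an, pairwise = pw, cosinor = cos_fit, environment = env_fit)
}

#' Run the full seasonal-variation analysis on a cohort
#'
#' Reproduces the analysis sequence on a synthetic or user-supplied cohort:
#' per-subject mean GM/WM fALFF (normalized, unfiltered signals), global and
#' per-network connectivity summaries (band-pass filtered, normalized
#' signals), binary graph metrics, nuisance residualization of every derived
#' measure, and for each measure the battery of season ANOVA, all pairwise
#' contrasts, the cosinor periodicity fit and (when an environment table is
#' available) the environmental regression.
#'
#' @param cohort An `fc_cohort`.
#' @param env Optional environment table; defaults to
#'   [generate_environment()] of the cohort's own configuration when the
#'   cohort is simulated.
#' @param measures Which measure families to compute: subset of
#'   `c("falff", "connectivity", "graph")`.
#' @param band Connectivity band-pass edges in Hz.
#' @param welch [welch_params()] for the spectral stage.
#' @param tau,threshold_mode Graph binarization threshold and mode.
#' @param alpha Significance level recorded in the provenance block.
#' @param residualize Nuisance covariate column to regress out of every
#'   measure (`"sex"`, or `NULL` to skip).
#'
#' @return An object of class `seasonfc_results`: list with `measures` (one
#'   row per subject, one column per derived measure, nuisance-adjusted),
#'   `anova`, `pairwise`, `cosinor` (glance rows; fitted objects under
#'   `cosinor_fits`), `environment` tibbles, `network` and `per_gm_region`
#'   connectivity tables, `graph` metrics table, and a `provenance` list
#'   (config hash, package version, parameters).
#' @export
run_pipeline <- function(cohort,
                         env = NULL,
                         measures = c("falff", "connectivity", "graph"),
                         band = c(0.01, 0.1),
                         welch = welch_params(),
                         tau = 0.2,
                         threshold_mode = "raw",
                         alpha = 0.05,
                         residualize = "sex") {
  stopifnot(inherits(cohort, "fc_cohort"))
  if (nrow(cohort$subjects) == 0) abort("empty cohort")
  measures <- match.arg(measures, several.ok = TRUE)
  if (is.null(env) && !is.null(cohort$ground_truth)) {
    env <- generate_environment(cohort$ground_truth)
  }

  tab <- cohort$subjects
  network <- NULL
  per_gm <- NULL
  graph <- NULL

  if ("falff" %in% measures) {
    fal <- cohort_falff(cohort, params = welch)
    tab <- dplyr::left_join(tab, fal[c("id", "falff_gm", "falff_wm")], by = "id")
  }
  if ("connectivity" %in% measures) {
    conn <- cohort_connectivity(cohort, low_hz = band[1], high_hz = band[2])
    tab <- dplyr::left_join(
      tab, conn$global[c("id", "z_gm_wm", "z_gm_gm", "z_wm_wm")], by = "id"
    )
    network <- conn$network
    per_gm <- conn$per_gm_region
  }
  if ("graph" %in% measures) {
    graph <- cohort_graph_metrics(
      cohort, tau = tau, mode = threshold_mode,
      low_hz = band[1], high_hz = band[2]
    )
    wide <- graph |>
      tidyr::pivot_wider(
        id_cols = "id", names_from = "matrix_kind",
        values_from = c("density", "transitivity", "global_efficiency",
                        "characteristic_path_length")
      )
    tab <- dplyr::left_join(tab, wide, by = "id")
  }

  measure_cols <- setdiff(names(tab), c("id", "sex", "season", "year"))
  # simulated additive sex effect enters the derived measures, never the raw
  # signals: it exists to exercise the nuisance residualization below
  gt <- cohort$ground_truth
  if (!is.null(gt) && gt$sex_effect != 0) {
    for (m in measure_cols) {
      tab[[m]] <- tab[[m]] + gt$sex_effect * (tab$sex == "M")
    }
  }
  if (!is.null(residualize)) {
    ok <- measure_cols[vapply(tab[measure_cols],
                              function(v) !anyNA(v) && sd(v) > 0, logical(1))]
    tab <- residualize_measures(tab, ok, covariate = residualize)
  }

  usable <- measure_cols[vapply(tab[measure_cols],
                                function(v) !anyNA(v) && sd(v) > 0, logical(1))]
  batteries <- purrr::map(
    setNames(usable, usable),
    function(m) measure_battery(tab, m, env, alpha)
  )

  anova_tbl <- purrr::imap_dfr(batteries, function(b, m) {
    dplyr::mutate(glance(b$anova), measure = m, .before = 1)
  })
  pairwise_tbl <- purrr::imap_dfr(batteries, function(b, m) {
    dplyr::mutate(b$pairwise, measure = m, .before = 1)
  })
  cosinor_tbl <- purrr::imap_dfr(batteries, function(b, m) {
    dplyr::mutate(glance(b$cosinor), measure = m, .before = 1)
  })
  env_tbl <- if (!is.null(env)) {
    purrr::imap_dfr(batteries, function(b, m) {
      dplyr::mutate(glance(b$environment), measure = m, .before = 1)
    })
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("seasonfc")),
    config_hash = rlang::hash(list(
      ground_truth = if (!is.null(gt)) unclass(gt),
      subjects = cohort$subjects, band = band, welch = unclass(welch),
      tau = tau, threshold_mode = threshold_mode, alpha = alpha,
      residualize = residualize, measures = measures
    )),
    alpha = alpha, band = band, tau = tau, threshold_mode = threshold_mode,
    residualize = residualize,
    seed = if (!is.null(gt)) gt$seed
  )

  structure(
    list(
      measures = tab,
      anova = anova_tbl,
      pairwise = pairwise_tbl,
      cosinor = cosinor_tbl,
      environment = env_tbl,
      network = network,
      per_gm_region = per_gm,
      graph = graph,
      cosinor_fits = purrr::map(batteries, "cosinor"),
      provenance = provenance
    ),
    class = "seasonfc_results"
  )
}

#' @export
print.seasonfc_results <- function(x, ...) {
  cat("<seasonfc_results>\n")
  cat(sprintf("  %d subjects, %d measures; config %s\n",
              nrow(x$measures), nrow(x$anova), x$provenance$config_hash))
  cat("  ANOVA (per measure):\n")
  print(x$anova[c("measure", "f_statistic", "p_value", "cohens_f")], n = 5)
  invisible(x)
}

#' Write a results bundle as CSV/JSON files
#'
#' Every table gains a `config_hash` column so each row is traceable to the
#' run that produced it.
#'
#' @param results A `seasonfc_results` object.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "seasonfc_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- results$provenance$config_hash
  tables <- c("measures", "anova", "pairwise", "cosinor", "environment",
              "network", "per_gm_region", "graph")
  for (nm in tables) {
    t <- results[[nm]]
    if (is.null(t)) next
    t$config_hash <- h
    readr::write_csv(t, file.path(dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(results$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
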