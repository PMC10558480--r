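# seasonfc

Seasonal variation analysis of resting-state functional connectivity and
BOLD fluctuation amplitude, for region-averaged fMRI time series.

Resting-state measures are usually treated as stable subject traits, but if
they drift with the season of acquisition, seasonality silently confounds
any study that pools scans across the year. `seasonfc` implements the full
analysis chain needed to detect and quantify such drift, plus a synthetic
cohort generator with injectable seasonal effects so every stage can be
validated without access to restricted imaging data.

## What it computes

Starting from per-subject timepoints × regions tables (gray-matter regions
and white-matter bundles, TR-sampled BOLD):

- **fALFF** — Welch power spectral density on normalized, unfiltered
  signals; fractional amplitude = power in 0.01–0.08 Hz over power above
  0.01 Hz; per-subject mean GM and WM fALFF.
- **Functional connectivity** — 4th-order zero-phase Butterworth band-pass
  (0.01–0.1 Hz), unit-variance normalization, Pearson matrices for
  WM × GM, GM × GM, WM × WM, Fisher Z transform, and mean |Z| summaries
  globally, per functional network, and per GM region (WM-averaged).
- **Graph topology** — correlation matrices thresholded at r > 0.2 and
  binarized; density, transitivity (tr(X³) / (ΣX² − trX²)), global
  efficiency (mean 1/d over pairs), characteristic path length (mean d
  over reachable pairs), all oracle-validated.
- **Seasonal inference** — acquisition quarters coded t = 0, 1, 2, 3
  (winter → autumn, ω = 2π/4); for every nuisance-adjusted measure: one-way
  season ANOVA with Cohen's f, pooled-t pairwise contrasts with Cohen's d,
  the cosinor fit

  y(t) = a·sin(ωt) + b·cos(ωt) + c  ≡  A·cos(ωt + ϑ) + c,  A = √(a²+b²),

  with an F-test of seasonal periodicity (df 2, n − 3) and a 95 %
  confidence band, and a regression on seasonal mean temperature and
  daylength.

## Worked example

Simulate a cohort with a 40 % autumn-peaking gain on the shared
low-frequency component, run the full pipeline, and inspect the seasonal
statistics:

```r
library(seasonfc)

cfg <- simulation_config(
  n_per_season = c(30, 30, 30, 30), n_gm_regions = 10, n_wm_regions = 6,
  n_networks = 5, n_timepoints = 400, n_latents = 4,
  amp_true = 0.4, phase_true = phase_for_peak("autumn"), seed = 2026
)
cohort  <- generate_cohort(cfg)
results <- run_pipeline(cohort)

dplyr::filter(results$anova, measure %in% c("falff_gm", "falff_wm", "z_gm_wm"))
#>   measure  f_statistic  p_value cohens_f
#> 1 falff_gm        297. 2.91e-54     2.77
#> 2 falff_wm        249. 2.06e-50     2.54
#> 3 z_gm_wm         184. 6.04e-44     2.18

dplyr::filter(results$cosinor, measure %in% c("falff_gm", "z_gm_wm"))
#>   measure  amplitude phase peak_season  p_value
#> 1 falff_gm    0.115   1.56 autumn      1.43e-54
#> 2 z_gm_wm     0.0734  1.54 autumn      6.68e-44
```

Both mean GM fALFF and global GM–WM connectivity vary strongly across
seasons (large F, Cohen's f), the fitted cosinor peaks in autumn, and the
recovered phase (≈ 1.56 rad) matches the injected `phase_for_peak("autumn")`
(π/2). The summer-vs-autumn contrast on global mean |Z| is

```r
dplyr::filter(results$pairwise, measure == "z_gm_wm",
              season_a == "summer", season_b == "autumn")
#>   t_stat    df  p_value cohens_d mean_diff
#> 1  -11.0    58 8.55e-16    -2.84   -0.0648
```

i.e. autumn connectivity exceeds summer by 2.8 pooled standard deviations
at this (deliberately large) injected amplitude. `autoplot()` on
`results$cosinor_fits$falff_gm` draws the group means ± SEM with the fitted
sinusoid and its confidence band; `generics::tidy()` / `glance()` work on
every fitted object.

With `amp_true = 0`, the same battery holds its nominal type-I error —
that, and the recovery behaviour above, are what the acceptance checks
quantify.

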