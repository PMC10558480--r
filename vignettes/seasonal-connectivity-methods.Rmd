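---
title: "Methods: seasonal variation analysis of resting-state connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal variation analysis of resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasonfc)
```

## The scientific question

Resting-state fMRI measures — the amplitude of spontaneous low-frequency
BOLD fluctuations and the correlation structure between brain regions — are
usually treated as stable subject characteristics. If they instead drift
with the season of acquisition, seasonality becomes a confound for any
study that pools scans across the year. `seasonfc` implements the analysis
chain needed to quantify such effects on region-averaged BOLD time series:
spectral amplitude (fALFF), gray-matter (GM) / white-matter (WM) functional
connectivity, binary graph topology, and a quarter-coded sinusoidal
(cosinor) model of seasonal periodicity, together with a synthetic cohort
generator that injects known seasonal effects so the whole chain can be
validated end to end.

## Measures

**fALFF.** For each region the power spectral density is estimated with
Welch's averaged-periodogram method on the *normalized but unfiltered*
signal (filtering first would empty the denominator band by construction).
fALFF is the ratio of total estimated power in 0.01–0.08 Hz (band edges
included) to total power at frequencies strictly above 0.01 Hz, a number in
[0, 1]. The phrase "average power" in common fALFF descriptions is
ambiguous between per-bin means and band sums; per-bin means would make a
flat spectrum score 1 rather than the conventional band-fraction (about
0.10 at TR = 0.72 s), so the sum convention — the standard fALFF
definition — is used, and the denominator's strict lower edge follows the
"higher than 0.01 Hz" reading. With the default grid (1200 samples split
into 8 Hamming-tapered segments at 50 % overlap, segment length 266) the
numerator holds 14 bins and the denominator 132, so white noise scores
14/132 ≈ 0.106, within a few percent of the continuum ratio
0.07/(0.694 − 0.01) ≈ 0.102. Welch defaults (8 segments, 50 % overlap,
Hamming) mirror the common MATLAB `pwelch` configuration and are
configurable via `welch_params()`. The estimator satisfies Parseval's
identity (`sum(power) * delta_f` ≈ variance) and reduces exactly to the
one-sided periodogram for one rectangular segment; both properties are
tested.

**Connectivity.** Signals are band-pass filtered to 0.01–0.1 Hz with a
4th-order Butterworth filter applied forward and backward (zero phase, so
correlation structure is not shifted; the filter family and order are
recorded choices, not claims about any particular preprocessing pipeline),
then normalized to zero mean and unit variance. Pearson matrices are formed
for WM × GM, GM × GM and WM × WM region pairs, Fisher Z-transformed
(`atanh`, with |r| clipped at 1 − 1e−7 so unit diagonals cannot produce
infinities), and summarized as the mean of |Z|. For square within-tissue
matrices the unit diagonal and the duplicate lower triangle are excluded —
including the diagonal would add a constant inflation to every subject —
while cross-tissue rectangular matrices use all elements. The WM × GM
matrix is additionally summarized per functional network (mean |Z| over the
network's GM columns) and per GM region (mean |Z| over all WM rows).

**Graph topology.** Each square correlation matrix is thresholded at
τ = 0.2 and binarized. Thresholding applies to the raw correlation (edge
iff r > 0.2), not the Fisher Z value, and negative correlations do not form
edges by default; an `absolute` mode is provided because the treatment of
negative correlations is a genuinely open convention. On the resulting
graph the package computes density (present / possible edges), transitivity
(tr(X³) over the number of connected triplets, `sum(X²) − tr(X²)`), global
efficiency (mean inverse shortest-path length over ordered pairs, with
unreachable pairs contributing zero), and characteristic path length (mean
shortest-path length over *reachable* unordered pairs only). Shortest paths
come from breadth-first search; every metric is cross-checked in the test
suite against triplet enumeration, a Floyd–Warshall oracle, and igraph.

## Seasonal inference

Seasons are the acquisition quarters: spring Feb 1 – Apr 30, summer May 1 –
Jul 31, autumn Aug 1 – Oct 31, winter Nov 1 – Jan 31; a winter spans the
year boundary, so November–December dates keep their calendar year as the
cohort year and January dates inherit the preceding one.

All inference operates on per-subject derived measures after nuisance
residualization (ordinary least squares on the covariate plus intercept,
grand mean added back; sex by default). The battery applied uniformly to
every measure is:

1. **One-way ANOVA** across the four season groups, with Cohen's
   f = sqrt(η²/(1 − η²)), η² = SS_between/SS_total. The Cohen's f
   convention is stated explicitly because several exist.
2. **Pairwise contrasts**: pooled-variance Student's t with Cohen's
   d = mean difference / pooled SD (consistent estimator pair). No
   multiplicity correction is applied by default, matching the uncorrected
   reporting convention for seasonal pairwise comparisons; corrections can
   be applied downstream to the returned p-values.
3. **Cosinor fit**: y = a·sin(ωt) + b·cos(ωt) + c with t = 0, 1, 2, 3 for
   winter → autumn and ω = 2π/4 (the period is fixed to one year expressed
   in quarters). Amplitude A = sqrt(a² + b²) and phase ϑ satisfy
   b = A·cos ϑ, a = −A·sin ϑ, ϑ ∈ (−π, π], so the fitted curve is
   A·cos(ωt + ϑ) + c and its peak quarter is argmax over t. Significance of
   periodicity is the F-test of the sine and cosine terms jointly against
   the intercept-only model, df (2, n − 3), with each subject as one
   observation (group means are used only for plotting). The 95 %
   confidence band is the standard OLS pointwise band for the mean response
   over continuous t ∈ [0, 4).
4. **Environmental regression**: the sinusoidal regressors are replaced by
   the mean temperature and mean daylength of each subject's season-year;
   per-coefficient t-tests and the overall F are reported, with Cohen's
   f = sqrt(R²/(1 − R²)). A condition-number guard (κ > 1e8 on the scaled
   design) rejects collinear environments rather than returning unstable
   coefficients. A `lag_quarters` flag shifts the environmental lookup
   backwards for exploration; the default is 0.

## The synthetic cohort generator

No generative model of seasonal BOLD data exists to copy, so the
generator's distributional choices are the package's own, built to be the
*minimal* mechanism that produces the phenomena the analysis must detect:

- Each subject receives `n_latents` latent signals (white noise band-pass
  filtered to 0.01–0.08 Hz) shared across regions through a loading matrix
  drawn once per cohort, plus independent white noise per region. The
  shared latents create the inter-regional correlation backbone; fixing
  loadings across subjects keeps that backbone stable so group contrasts
  are meaningful.
- The seasonal effect is one multiplicative gain,
  1 + amp·cos(2π·t/4 + phase), applied to the latent component only. A
  single parameter therefore raises both low-frequency power (fALFF) and
  inter-regional correlation in the peak season — mirroring joint
  fALFF/connectivity seasonality without asserting a physiological
  mechanism. `amp < 1` keeps the gain positive.
- Defaults mirror the modelled study conditions: season groups of
  127/99/91/93 subjects, 90 GM regions in 14 networks, 48 WM bundles, 1200
  timepoints at TR = 0.72 s, 60 % female, two winter-to-autumn acquisition
  cycles. With `n_latents = 8`, `loading_scale = 1.1` and `noise_sd = 1`
  the latent (signal) variance roughly equals the noise floor — a
  signal-to-noise ratio typical of region-averaged BOLD.
- A simulated sex effect is an additive offset on derived measures, not on
  raw signals: its only purpose is to exercise nuisance residualization.
- The environment table follows mean + amplitude·cos(2π(t − peak)/4) over
  quarters. Daylength is deterministic (astronomically fixed across years)
  while temperature receives small seeded year-to-year deviations (sd
  1.5 °C by default). This is both realistic and necessary: with two exact
  cosines of the same peak the two regressors would be perfectly collinear
  and the environmental regression unidentifiable by design.
- Determinism: one master seed spawns per-subject sub-seeds, so identical
  configurations give bit-identical cohorts and result tables.

What the generator does **not** emulate: hemodynamic autocorrelation and
1/f spectral shape, motion and physiological artifacts, spatial structure
within regions, inter-subject anatomical variability, and any asymmetric
(non-sinusoidal) seasonal profile. Passing tests therefore demonstrate that
the *analysis chain* recovers injected effects of the assumed form under
realistic SNR — not that real brains behave this way.

## Numerical choices and degenerate inputs

- Constant regions are rejected by name in normalization and correlation;
  empty season groups, rank-deficient cosinor designs (fewer than 3
  seasons) and collinear environments raise errors rather than silently
  degrading.
- Zero-denominator transitivity (no paths of length 2) errors by default;
  cohort-level graph summaries opt into the 0 convention so that degenerate
  subject graphs remain rows in the table (with `NA` path length when no
  edge exists).
- Fisher-Z clipping events other than the expected unit diagonal trigger a
  warning.
- Singleton season groups report `NA` standard errors with a warning
  instead of failing.

## Problem sizes used in validation

The test-suite and acceptance-script simulations run at reduced
dimensionality chosen once for statistical adequacy: Monte-Carlo cosinor
checks use 100 subjects per season on unit-noise measures (200 recovery
replicates, 2000 null replicates); the generator-to-inference loop uses 100
subjects per season with 6 GM + 4 WM regions, 4 latents and 256 timepoints
(100 replicates); module tests use smaller cohorts still. Region and
timepoint counts enter those checks only through estimation noise, so the
reduced sizes preserve the properties being tested while keeping repeated
simulation practical.

At the cosinor check's low signal-to-noise ratio (amplitude 0.1 against
unit noise, 100 subjects/season) the amplitude estimator is
Rice-distributed with mean ≈ 0.128 and the periodicity F-test has
noncentrality 2 (power ≈ 0.22); the test suite pins the Monte-Carlo results
to these closed forms. Detection power and near-unbiased amplitude recovery
appear at larger effects, as in the amplitude-0.3 end-to-end check.

## Limitations

- The cosinor model is symmetric by construction; asymmetric seasonal
  profiles are only approximated by their first harmonic.
- Four discrete quarters cannot resolve phase more finely than the quarter
  width; phase estimates should be read as "peak quarter" statements.
- With quarterly resolution, temperature and daylength are nearly
  collinear in realistic climates; their separate coefficients are
  identifiable only through year-to-year variation and should be
  interpreted jointly.
- Binary graph metrics depend on the (conventional) threshold τ = 0.2;
  no proportional-thresholding sweep is implemented.
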