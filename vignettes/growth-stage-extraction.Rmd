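---
title: "Extracting maize growth stages from NDVI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting maize growth stages from NDVI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomaize)
```

## The problem and the model

A maize pixel observed through a season of NDVI composites traces a
unimodal curve: low over bare soil, a steep rise through vegetative growth,
a broad plateau around peak biomass, and a decline through senescence.
Three agronomic dates are read off that curve's shape:

* **jointing** — the rising inflection, where canopy growth is fastest
  (maximum positive slope);
* **tasseling** — the seasonal peak, where the slope crosses zero;
* **maturity** — the falling inflection, where senescence is fastest
  (maximum negative slope).

The package assumes a *single-season* crop (one peak per year), composites
on a uniform 8-day grid (26 samples covering roughly April–October, DOY
97–297), and a per-sample validity weight in {0, 1} marking cloud-flagged
or missing composites. Multi-season and double-cropping curves are out of
scope, as are threshold-based start/end-of-season metrics.

## Smoothing

Composites are noisy (residual clouds, aerosols, view geometry), so the
series is smoothed before any derivative is taken. Two filters are
provided, with the same interface and interchangeable in the pipeline.

**Savitzky–Golay** (`sg_smooth()`): a moving-window least-squares
polynomial fit expressed as a fixed convolution. Defaults: half-window
`m = 2` (five composites, a 40-day window) and `poly_order = 2` — the
narrowest window that still suppresses single-composite outliers while a
quadratic can track the curvature at the season's shoulders. The ends of
the series are mirror-padded by `m` samples so the output keeps the input
length; cloud-flagged samples are linearly gap-filled from their nearest
valid neighbours first, because the convolution assumes uniformly valid
sampling.

**Whittaker** (`whittaker_smooth()`): discrete penalized least squares,
minimizing fidelity plus `lambda` times the summed squared third
differences. The difference order defaults to `d = 3` (the penalty's null
space is then a quadratic, matching a season shoulder); the classical
`d = 2` variant is available through `diff_order`. Weight-0 samples carry
no fidelity weight and are bridged by the penalty itself. The system
`(W + lambda D'D) z = W y` is symmetric positive definite for `lambda > 0`
with at least one valid sample; an all-flagged series is a degenerate-input
error.

**Choosing lambda.** `select_lambda()` scores each candidate on a log grid
(default 13 points over `1e-1 ... 1e4`) by the mean squared leave-one-out
residual over the valid samples and returns the minimizer, breaking ties
toward the smallest `lambda` (prefer fidelity when the CV curve is flat).
Because the smoother is linear in the data, the LOO residual is computed
exactly from a single fit via the leverage identity
`(y_i - z_i) / (1 - h_ii)`; the test suite checks this against explicit
leave-one-out refits. Selecting by the raw residual against the observed
data would be degenerate (it is minimized by no smoothing at all), so
cross-validation is the interpretation adopted for "the lambda with the
smallest error". Note that LOO targets *prediction* of held-out
composites; for batch runs over many pixels the pipeline also accepts a
fixed mid-grid value (`lambda = 10` is the batch default used in the
scene-scale tests), which costs one linear solve per pixel-year instead of
thirteen and behaves almost identically for the sharp features.

## Daily interpolation

`spline_daily()` fits the natural cubic spline (zero second derivative at
the season edges — no derivative information exists there) through the
smoothed composites and evaluates it, with its analytic first derivative,
at every integer DOY. The analytic derivative, not a finite difference of
daily values, feeds the detectors; this removes 1-day quantization noise
from the node search. No extrapolation is performed outside the knot range.

## Stage detection

`extract_stages()` composes smoothing, interpolation and three detectors
inside a season window (default DOY 97–297, configurable):

* `detect_tasseling()` — the DOY of the window's global maximum, required
  to be an interior peak (rising slope somewhere before, falling slope
  somewhere after); a maximum on the window boundary is flagged
  `edge_peak`.
* `detect_jointing()` / `detect_maturity()` — the DOY of the extreme
  derivative before/after the peak. The extremum must be an *interior
  local* extremum of the derivative: an inflection is by definition a
  local extremum of slope, whereas a derivative that keeps steepening up to
  the boundary of the search interval is an artifact of the fitted tail.
  Two safeguards follow from this view. First, leading and trailing
  weight-0 composites are trimmed before smoothing — with `d = 3` the
  penalty would extrapolate the senescence limb quadratically into the
  unobserved tail, and that fabricated, ever-steepening slope otherwise
  masquerades as the maturity inflection. Second, when no interior local
  extremum exists the stage is reported undetected (`edge_peak`) rather
  than assigned to the boundary day.

Every tie breaks to the earliest DOY, for determinism. Series whose
smoothed seasonal amplitude is below `amplitude_min` (default 0.2 NDVI)
are rejected as non-crop or failed pixels (`low_amplitude`); the threshold
is configurable. Multiple local maxima are resolved by the global maximum,
appropriate for a single-season crop.

## Trend, correlation and validation analytics

Per-pixel interannual analysis uses the OLS slope of stage DOY on year
(days/year; negative = advancing) and the Pearson correlation with monthly
covariates, with a two-sided t-test (`t = r sqrt((n-2)/(1-r^2))`,
`n - 2` df) classified at the 0.05 and 0.01 levels. Missing years are
removed by pairwise-complete deletion (no imputation); pixels with fewer
than three complete pairs are undetected. No multiple-testing correction
is applied across pixels — per-pixel raw p-values are reported as such.

Meteorological cubes hold monthly values: land-surface temperature as the
monthly mean of all available observations (day and night overpasses
pooled equally, Kelvin converted to Celsius on request) and precipitation
as the monthly sum. Cubes on a foreign grid are regridded by
nearest-neighbour assignment (each target cell takes the value of the
source cell containing its centre) — values are conserved, never
interpolated. Stages are paired with the covariate of the month preceding
the month they occur in (jointing/June with May, tasseling/July with June,
maturity/September with August; the lag is configurable). The dominant
factor at a pixel is whichever covariate has the larger absolute
correlation; exact ties go to precipitation, an arbitrary but documented
rule kept for determinism.

Validation compares extracted and observed stage DOYs by RMSE, MAE and
MAPE. MAPE uses the observed date in the denominator (the ground-truth
convention); at DOY scale the two possible orderings differ by less than
0.1%. DOY-class area summaries use half-open bins `[lo, hi)` with open
outer classes, so fractions always sum to one; the default interior edges
are the 16-day windows 161/177, 201/217 and 257/273 for jointing,
tasseling and maturity.

## The synthetic-scene generator

`generate_scene()` emulates the study inputs so every pipeline stage is
testable without downloads. Each pixel-year follows a double-logistic
curve — the canonical unimodal crop trajectory, chosen because its
inflection structure gives (numerically) analytic ground truth:

`NDVI(t) = v_min + (v_max - v_min) [sigma(m1 (t - s1)) + sigma(-m2 (t - s2)) - 1]`

Defaults: `v_min = 0.15`, `v_max = 0.85` (a healthy maize canopy over
soil), green-up rate `m1 = 0.10`/day, senescence rate `m2 = 0.08`/day,
inflections around DOY 165 and 262 with pixel-year jitter (Gaussian
`sd = 4` days, or uniform half-range), optional interannual drift in
days/year, additive Gaussian noise (`sd = 0.03` NDVI), and independent
per-composite cloud dropouts (probability 0.1) whose values are both
flagged (weight 0) and depressed, as clouds depress apparent NDVI. True
stage dates come from a 0.01-day-resolution search on the noise-free
curve. Site observations are sampled from the truth; monthly covariates
mix the standardized true stage DOYs with independent noise so their
pixelwise correlation with the truth equals the configured coupling in
expectation (temperature coupled at -0.6 by default, precipitation
independent). Scenes are byte-reproducible from `(config, seed)`.

What the generator does *not* emulate: spatially correlated noise and
cloud fields, mixed pixels at 250 m, saturation of NDVI over dense
canopies, multi-year planting-distribution change, and real weather
dependence of the curve shape. Passing tests therefore demonstrate
correctness of the algorithms under the stated noise model, not
performance on any particular satellite archive.

## Numerical choices and problem sizes

Integer DOYs are 1-based (Jan 1 = 1); pixel indices are 1-based, row 1 =
north; stage rasters encode undetected as -9999 on disk, statistics as
`NA`. Cube persistence uses a plain-text container (JSON metadata plus CSV
tables with `%.17g` serialization) so write-then-read round-trips are
exact. The test suite exercises the smoothers against dense-matrix and
sliding-window oracles at 1e-10/1e-12, the heavy-smoothing limit against a
global quadratic fit at 1e-3, and the recovery experiments at the sizes a
single CPU handles in seconds: 200 pixel-years for the noisy stage-error
experiment and a 500-pixel, 20-year scene for trend-, coupling- and
calibration-recovery.

## Known limitations

Stage dates are argument-of-extremum features, and their detectability is
bounded by the local curvature of the seasonal curve relative to the noise
left after smoothing. The tasseling peak of a broad-plateau season has
near-zero curvature, and the senescence derivative at gentle senescence
rates is flat over a week or more; around such flat features, single
pixel-year dates can be off by many days even with well-chosen smoothing,
with occasional large excursions — errors shrink with steeper seasonal
dynamics, lower noise and fewer dropouts, and average out in multi-year
trend estimates. Asymmetric upper-envelope reweighting (for negatively
biased cloud noise), function-fitting smoothers, Sen's slope/Mann-Kendall
trends and spatial-autocorrelation corrections are deliberately out of
scope.
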