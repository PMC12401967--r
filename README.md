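# phenomaize

Maize growth-stage extraction from NDVI composite time series.

Regional crop monitoring needs the dates of the key maize growth stages —
jointing (rapid stem elongation), tasseling (the vegetative-to-reproductive
transition) and physiological maturity — over whole scenes and decades,
which field observation cannot provide. `phenomaize` extracts those dates
per pixel and year from 8-day NDVI composites (26 per April–October season,
MODIS-style), and provides the downstream analytics used in land-surface
phenology studies: interannual trends, correlations with preceding-month
meteorological covariates, dominant-factor maps, DOY-class area summaries
and validation against site observations. A synthetic-scene generator with
analytic ground truth makes the whole pipeline testable without any
satellite archive.

## Method

Each pixel-year series \(y\) (with per-sample cloud weights
\(w_i \in \{0,1\}\)) is denoised by one of two filters:

* **Savitzky–Golay**: the moving-window least-squares convolution
  \(Y_j' = \sum_{i=-m}^{m} C_i\,Y_{j+i} / N\) with window \(N = 2m+1\)
  (default \(m = 2\), quadratic fit, mirror padding at the season edges;
  cloud-flagged samples are linearly gap-filled first).
* **Whittaker**: penalized least squares, minimizing
  \(Q = S + \lambda R\) with fidelity \(S = \sum_i w_i (y_i - z_i)^2\) and
  roughness \(R = \sum_i (\Delta^3 z_i)^2\), solved from
  \((W + \lambda D^\top D)\,z = W y\). The smoothing parameter is chosen by
  exact leave-one-out cross-validation over a log grid
  \(10^{-1}\ldots10^{4}\).

The smoothed composites are interpolated to daily resolution with a natural
cubic spline, and stages are read off the spline's analytic first
derivative (the slope-feature-node method): tasseling at the interior
seasonal maximum (zero slope), jointing at the rising inflection (maximum
positive slope before the peak), maturity at the falling inflection
(maximum negative slope after it). Interannual change is summarized by the
OLS slope \(b\) of stage DOY on year (days/year; \(b < 0\) = advancing) and
by the Pearson correlation \(R_{xy}\) with monthly covariates, classified
by a two-sided t-test at the 0.05/0.01 levels. Extraction accuracy is
scored with RMSE, MAE and MAPE against observed stage dates.

## Worked example

```r
library(phenomaize)
doys <- seq(97, 297, by = 8)                    # 26 composites, April-October
set.seed(1)
v <- double_logistic(doys, s1 = 163, s2 = 265) + rnorm(26, 0, 0.03)
w <- rep(1L, 26); w[c(6, 14)] <- 0L             # two cloud-flagged composites
s <- ndvi_series(doys, pmin(pmax(v, -1), 1), w, year = 2022)

select_lambda(s)                 # LOO-CV pick from the default grid
#> [1] 1.778279
extract_stages(s, method = "whittaker")
#> <stage_dates> jointing 163, tasseling 209, maturity 267 [ok]
round(true_stage_dates(s1 = 163, s2 = 265), 2)  # the generating curve's truth
#>  jointing tasseling  maturity
#>    162.99    209.60    265.01
validation_metrics(c(170, 160), c(166, 168), stage = "jointing")
#> <validation_report> jointing n=2  RMSE 6.32 d  MAE 6.00 d  MAPE 3.59%
```

The detected DOYs (163 / 209 / 267) sit within two days of the analytic
inflection and peak dates of the noise-free curve; the validation report
shows the error metrics a site comparison produces.

Scene-level work goes through `generate_scene()` / `read_ndvi_cube()`,
`extract_stage_maps()`, `stage_trend_map()`, `correlate_stage_met()`,
`dominant_factor()` and `run_pipeline()`; a thin command-line front end
(`inst/cli/phenomaize`, subcommands `synth`, `run`, `validate`) drives the
same functions from a shell. See the methods vignette
(`vignettes/growth-stage-extraction.Rmd`) for the model, parameter and
design details.

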