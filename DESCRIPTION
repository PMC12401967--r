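Package: phenomaize
Title: Maize Growth-Stage Extraction from NDVI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Extracts the key maize growth stages (jointing, tasseling and
    maturity) from 8-day NDVI composite time series by Savitzky-Golay or
    Whittaker penalized-least-squares smoothing, daily cubic-spline
    interpolation and slope-feature-node detection. Includes per-pixel
    interannual trend and Pearson-correlation analytics against monthly
    meteorological covariates, validation metrics (RMSE/MAE/MAPE) against
    field observations, a synthetic-scene generator with analytic ground
    truth for end-to-end testing, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
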