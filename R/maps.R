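#' Extract stage-date maps from an NDVI cube
#'
#' Runs the per-pixel-year extraction ([extract_stages()]) over every masked
#' pixel and year of a cube, producing one `[row, col, year]` DOY array per
#' stage plus a quality-flag array. Pixel-years that fail (e.g. fully
#' cloud-flagged) are recorded as undetected with flag `"error"` rather than
#' aborting the scene.
#'
#' @param cube An [ndvi_cube()].
#' @param ... Passed to [extract_stages()] (method, window, smoother
#'   settings).
#' @return A list of class `stage_maps`: arrays `jointing`, `tasseling`,
#'   `maturity` (`NA` = undetected), character array `flag`, plus `years`
#'   and the cube's `mask`/`grid`.
#' @export
extract_stage_maps <- function(cube, ...) {
  stopifnot(inherits(cube, "ndvi_cube"))
  d <- dim(cube$values)
  ny <- length(cube$years)
  arr <- function() array(NA_real_, dim = c(d[1], d[2], ny))
  out <- list(jointing = arr(), tasseling = arr(), maturity = arr(),
              flag = array(NA_character_, dim = c(d[1], d[2], ny)),
              years = cube$years, mask = cube$mask, grid = cube$grid)
  for (yi in seq_len(ny)) {
    for (c_ in seq_len(d[2])) {
      for (r_ in seq_len(d[1])) {
        if (!isTRUE(cube$mask[r_, c_])) next
        res <- tryCatch({
          s <- cube_series(cube, r_, c_, cube$years[yi])
          extract_stages(s, ...)
        }, error = function(e) stage_dates(NA, NA, NA, "error"))
        out$jointing[r_, c_, yi] <- res$jointing
        out$tasseling[r_, c_, yi] <- res$tasseling
        out$maturity[r_, c_, yi] <- res$maturity
        out$flag[r_, c_, yi] <- res$quality_flag
      }
    }
  }
  class(out) <- "stage_maps"
  out
}

#' Per-pixel interannual trend of a stage-date map
#'
#' Fits the OLS slope of stage DOY on calendar year at each pixel
#' (days/year; negative = advancing), with the Pearson correlation and its
#' t-test classification. Pixels with fewer than 3 detected years come back
#' `NA`.
#'
#' @param stage_doys Numeric array `[nrow, ncol, n_years]`.
#' @param years Calendar years of the third dimension.
#' @return A `pixel_corr` list of matrices (`slope_b` in days/year).
#' @export
stage_trend_map <- function(stage_doys, years) {
  d <- dim(stage_doys)
  mat <- function(x) matrix(x, d[1], d[2])
  out <- list(r = mat(NA_real_), p_value = mat(NA_real_),
              slope_b = mat(NA_real_), n_used = mat(NA_integer_),
              significance = mat(NA_character_), covariate_month = NA_integer_)
  for (r_ in seq_len(d[1])) {
    for (c_ in seq_len(d[2])) {
      res <- tryCatch(trend_result(as.numeric(years), stage_doys[r_, c_, ]),
                      error = function(e) NULL)
      if (is.null(res)) next
      out$r[r_, c_] <- res$r
      out$p_value[r_, c_] <- res$p_value
      out$slope_b[r_, c_] <- res$slope_b
      out$n_used[r_, c_] <- res$n_used
      out$significance[r_, c_] <- res$significance
    }
  }
  class(out) <- "pixel_corr"
  out
}
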