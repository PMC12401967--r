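#' Aggregate sub-monthly meteorological samples to monthly covariates
#'
#' Collapses a stack of daily (or hourly) samples to the monthly covariates
#' the correlation analysis consumes: land-surface temperature becomes the
#' monthly mean of all available observations (day and night overpasses
#' pooled equally), with Kelvin converted to Celsius when `units = "K"`;
#' precipitation becomes the monthly sum of the sampled depths. A month
#' inside the sampled span with no samples yields `NA` with a warning.
#'
#' @param values Numeric array `[nrow, ncol, n_times]` of samples.
#' @param dates `Date` (or date-time) stamp per time slice.
#' @param variable `"lst_mean_monthly"` or `"precip_sum_monthly"`.
#' @param units Input units: `"C"` or `"K"` for LST, `"mm"` for
#'   precipitation.
#' @param grid Optional [grid_geometry()] carried through.
#' @return A [met_cube()].
#' @export
aggregate_monthly <- function(values, dates,
                              variable = c("lst_mean_monthly",
                                           "precip_sum_monthly"),
                              units = NULL, grid = NULL) {
  variable <- match.arg(variable)
  d <- dim(values)
  if (length(d) != 3L || d[3] != length(dates))
    stop("`values` must be [row, col, time] with one date per slice",
         call. = FALSE)
  if (is.null(units)) units <- if (variable == "lst_mean_monthly") "C" else "mm"
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  years <- sort(unique(yr))
  out <- array(NA_real_, dim = c(d[1], d[2], length(years), 12L))
  span <- range(yr * 12L + mo)
  for (yi in seq_along(years)) {
    for (m in 1:12) {
      code <- years[yi] * 12L + m
      if (code < span[1] || code > span[2]) next
      sel <- which(yr == years[yi] & mo == m)
      if (length(sel) == 0L) {
        warning(sprintf("no samples for %d-%02d; month left missing",
                        years[yi], m), call. = FALSE)
        next
      }
      slab <- values[, , sel, drop = FALSE]
      out[, , yi, m] <- if (variable == "lst_mean_monthly")
        apply(slab, c(1, 2), mean) else apply(slab, c(1, 2), sum)
    }
  }
  if (variable == "lst_mean_monthly" && identical(units, "K"))
    out <- out - 273.15
  met_cube(out, years = years, grid = grid, variable = variable)
}

#' Regrid a meteorological cube to the analysis grid
#'
#' Nearest-neighbour assignment: each target cell takes the value of the
#' source cell containing its centre; values are copied, never interpolated,
#' so coarse covariates are conserved when refined onto the 250 m NDVI grid.
#' Target cells whose centre falls outside the source extent become `NA`;
#' fully disjoint extents are an error.
#'
#' @param cube A [met_cube()] with a grid.
#' @param target_grid The [grid_geometry()] to resample onto.
#' @return A [met_cube()] on `target_grid`.
#' @export
regrid_to_analysis <- function(cube, target_grid) {
  stopifnot(inherits(cube, "met_cube"), inherits(target_grid, "grid_geometry"))
  if (is.null(cube$grid)) stop("source cube has no grid geometry", call. = FALSE)
  nr <- target_grid$nrow; nc <- target_grid$ncol
  rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ctr <- grid_center(target_grid, rc$row, rc$col)
  src <- grid_locate(cube$grid, ctr$x, ctr$y)
  if (all(is.na(src$row)))
    stop("disjoint extents: no target cell centre falls inside the source grid",
         call. = FALSE)
  d <- dim(cube$values)
  out <- array(NA_real_, dim = c(nr, nc, d[3], 12L))
  ok <- which(!is.na(src$row))
  for (yi in seq_len(d[3])) {
    for (m in 1:12) {
      layer <- cube$values[, , yi, m]
      tgt <- matrix(NA_real_, nr, nc)
      tgt[cbind(rc$row[ok], rc$col[ok])] <- layer[cbind(src$row[ok], src$col[ok])]
      out[, , yi, m] <- tgt
    }
  }
  met_cube(out, years = cube$years, grid = target_grid, variable = cube$variable)
}

#' Per-pixel correlation between stage dates and a preceding-month covariate
#'
#' For each pixel, the Pearson correlation (with OLS slope and t-test
#' significance) between the annual stage DOY series and the covariate of
#' the month `lag_months` before the month the stage occurs in (jointing,
#' tasseling and maturity occur in June, July and September, so the default
#' lag of 1 pairs them with May, June and August). Years are matched between
#' the two cubes and missing years dropped pairwise; pixels with fewer than
#' 3 complete pairs (or degenerate variance) come back `NA`.
#'
#' @param stage_doys Numeric array `[nrow, ncol, n_years]` of stage DOYs.
#' @param years Calendar years of the third dimension.
#' @param met A [met_cube()] on the same pixel grid.
#' @param stage_month Calendar month the stage occurs in.
#' @param lag_months Months of lag (default 1: the preceding month).
#' @return A list of class `pixel_corr`: matrices `r`, `p_value`, `slope_b`,
#'   `n_used`, character matrix `significance`, and `covariate_month`.
#' @export
correlate_stage_met <- function(stage_doys, years, met, stage_month,
                                lag_months = 1L) {
  stopifnot(inherits(met, "met_cube"))
  m <- as.integer(stage_month) - as.integer(lag_months)
  if (m < 1L || m > 12L)
    stop("covariate month out of range; check `stage_month`/`lag_months`",
         call. = FALSE)
  d <- dim(stage_doys)
  if (!identical(d[1:2], dim(met$values)[1:2]))
    stop("stage and met grids differ in shape", call. = FALSE)
  yidx <- match(years, met$years)
  if (all(is.na(yidx))) stop("no overlapping years", call. = FALSE)
  mat <- function(x) matrix(x, d[1], d[2])
  out <- list(r = mat(NA_real_), p_value = mat(NA_real_),
              slope_b = mat(NA_real_), n_used = mat(NA_integer_),
              significance = mat(NA_character_), covariate_month = m)
  for (r_ in seq_len(d[1])) {
    for (c_ in seq_len(d[2])) {
      y <- stage_doys[r_, c_, ]
      x <- rep(NA_real_, length(years))
      has <- !is.na(yidx)
      x[has] <- met$values[r_, c_, yidx[has], m]
      res <- tryCatch(trend_result(x, y), error = function(e) NULL)
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

#' Dominant meteorological factor per pixel
#'
#' Labels each pixel by whichever covariate has the larger absolute Pearson
#' correlation with the stage DOY series. Exact ties go to precipitation (a
#' documented, arbitrary rule kept for determinism); a pixel missing one
#' correlation takes the other, and a pixel missing both stays undetected.
#'
#' @param r_temp,r_precip Matrices of per-pixel correlations with temperature
#'   and precipitation.
#' @param mask Optional logical mask for the area-fraction summary.
#' @return A list of class `dominant_factor_map`: character matrix `label`
#'   (`"temperature"`/`"precipitation"`/`NA`), matrix `r_win` (winning
#'   \eqn{|r|}), and data.frame `fractions`.
#' @export
dominant_factor <- function(r_temp, r_precip, mask = NULL) {
  if (!identical(dim(r_temp), dim(r_precip)))
    stop("correlation rasters must be aligned", call. = FALSE)
  at <- abs(r_temp); ap <- abs(r_precip)
  label <- matrix(NA_character_, nrow(r_temp), ncol(r_temp))
  label[!is.na(at) & is.na(ap)] <- "temperature"
  label[is.na(at) & !is.na(ap)] <- "precipitation"
  both <- !is.na(at) & !is.na(ap)
  label[both] <- ifelse(at[both] > ap[both], "temperature", "precipitation")
  r_win <- ifelse(label == "temperature", at, ap)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(r_temp), ncol(r_temp))
  lab <- label[mask & !is.na(label)]
  frac <- if (length(lab)) {
    tb <- table(factor(lab, levels = c("temperature", "precipitation")))
    data.frame(factor = names(tb), count = as.integer(tb),
               fraction = as.integer(tb) / length(lab),
               stringsAsFactors = FALSE)
  } else data.frame(factor = character(), count = integer(),
                    fraction = numeric())
  structure(list(label = label, r_win = r_win, fractions = frac),
            class = "dominant_factor_map")
}
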