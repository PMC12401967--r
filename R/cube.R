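#' Raster grid geometry
#'
#' Minimal north-up grid description: the top-left corner, the cell size and
#' the raster dimensions. Row 1 is the northernmost row; pixel centres are at
#' half-cell offsets.
#'
#' @param xmin,ymax Coordinates of the grid's top-left corner.
#' @param xres,yres Cell size (positive).
#' @param nrow,ncol Raster dimensions.
#' @return A `grid_geometry` list.
#' @export
grid_geometry <- function(xmin, ymax, xres, yres, nrow, ncol) {
  if (xres <= 0 || yres <= 0) stop("cell size must be positive", call. = FALSE)
  structure(list(xmin = xmin, ymax = ymax, xres = xres, yres = yres,
                 nrow = as.integer(nrow), ncol = as.integer(ncol)),
            class = "grid_geometry")
}

# centre coordinates of cell (row, col)
grid_center <- function(grid, row, col) {
  list(x = grid$xmin + (col - 0.5) * grid$xres,
       y = grid$ymax - (row - 0.5) * grid$yres)
}

# (row, col) of the cell containing point (x, y); NA outside the grid
grid_locate <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$xres) + 1
  row <- floor((grid$ymax - y) / grid$yres) + 1
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow |
    !is.finite(col) | !is.finite(row)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' NDVI composite cube
#'
#' A scene of NDVI composites: `values[row, col, band]` with bands ordered
#' year-major (band = (year index - 1) * 26 + composite index), a parallel
#' validity `weight` array, a crop `mask`, the composite DOY grid and the
#' grid geometry. This is the in-memory form of the pipeline's main input.
#'
#' @param values Numeric array `[nrow, ncol, n_years * n_doys]`.
#' @param weight Integer 0/1 array of the same shape (default all valid).
#' @param years Calendar years covered.
#' @param doys Composite DOYs within each year (default `seq(97, 297, 8)`).
#' @param mask Logical crop mask `[nrow, ncol]` (default all `TRUE`).
#' @param grid A [grid_geometry()] (optional).
#' @param nodata Nodata value used on disk for DOY rasters (default -9999).
#' @return An `ndvi_cube` object.
#' @export
ndvi_cube <- function(values, weight = NULL, years,
                      doys = seq(97L, 297L, by = 8L),
                      mask = NULL, grid = NULL, nodata = -9999) {
  d <- dim(values)
  if (length(d) != 3L) stop("`values` must be a 3-D array", call. = FALSE)
  years <- as.integer(years); doys <- as.integer(doys)
  if (d[3] != length(years) * length(doys))
    stop(sprintf("band count %d does not equal n_years (%d) x n_composites (%d)",
                 d[3], length(years), length(doys)), call. = FALSE)
  if (is.null(weight)) weight <- array(1L, dim = d)
  if (!identical(dim(weight), d))
    stop("`weight` must match `values` in shape", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  structure(list(values = values, weight = weight, years = years,
                 doys = doys, mask = mask, grid = grid, nodata = nodata),
            class = "ndvi_cube")
}

#' @export
print.ndvi_cube <- function(x, ...) {
  cat(sprintf("<ndvi_cube> %d x %d pixels, %d years x %d composites (%d bands)\n",
              dim(x$values)[1], dim(x$values)[2], length(x$years),
              length(x$doys), dim(x$values)[3]))
  invisible(x)
}

#' Band labels of an NDVI cube
#'
#' Maps each band index back to its (year, DOY) stamp.
#'
#' @param cube An [ndvi_cube()].
#' @return data.frame with `band`, `year`, `doy`.
#' @export
band_labels <- function(cube) {
  nd <- length(cube$doys)
  data.frame(band = seq_len(length(cube$years) * nd),
             year = rep(cube$years, each = nd),
             doy = rep(cube$doys, times = length(cube$years)))
}

#' Extract one pixel-year series from a cube
#'
#' @param cube An [ndvi_cube()].
#' @param row,col Pixel indices (1-based, row 1 = north).
#' @param year Calendar year.
#' @return An [ndvi_series()].
#' @export
cube_series <- function(cube, row, col, year) {
  yi <- match(year, cube$years)
  if (is.na(yi)) stop("year not in cube", call. = FALSE)
  bands <- (yi - 1L) * length(cube$doys) + seq_along(cube$doys)
  v <- cube$values[row, col, bands]
  w <- cube$weight[row, col, bands]
  w[!is.finite(v)] <- 0L
  v[!is.finite(v)] <- 0
  v[w == 1L] <- pmin(pmax(v[w == 1L], -1), 1)
  ndvi_series(cube$doys, v, w, year = year)
}

#' Monthly meteorological cube
#'
#' Monthly covariate raster stack: `values[row, col, year, month]`, with the
#' variable tag recording units (`lst_mean_monthly` in deg C,
#' `precip_sum_monthly` in mm).
#'
#' @param values Numeric array `[nrow, ncol, n_years, 12]` (`NA` = month not
#'   covered).
#' @param years Calendar years of dimension 3.
#' @param grid A [grid_geometry()] (optional).
#' @param variable `"lst_mean_monthly"` or `"precip_sum_monthly"`.
#' @return A `met_cube` object.
#' @export
met_cube <- function(values, years, grid = NULL,
                     variable = c("lst_mean_monthly", "precip_sum_monthly")) {
  variable <- match.arg(variable)
  d <- dim(values)
  if (length(d) != 4L || d[4] != 12L)
    stop("`values` must be a [row, col, year, 12] array", call. = FALSE)
  if (d[3] != length(years))
    stop("year dimension does not match `years`", call. = FALSE)
  if (variable == "precip_sum_monthly" && any(values < 0, na.rm = TRUE))
    stop("precipitation must be >= 0", call. = FALSE)
  structure(list(values = values, years = as.integer(years), grid = grid,
                 variable = variable),
            class = "met_cube")
}

#' @export
print.met_cube <- function(x, ...) {
  cat(sprintf("<met_cube> %s, %d x %d pixels, years %d-%d\n",
              x$variable, dim(x$values)[1], dim(x$values)[2],
              min(x$years), max(x$years)))
  invisible(x)
}
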