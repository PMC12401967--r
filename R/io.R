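# Plain-text cube container: a directory holding meta.json plus CSV value
# tables. Values are serialized with "%.17g" so doubles round-trip exactly.

fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_value_table <- function(values3d, path) {
  d <- dim(values3d)
  flat <- matrix(values3d, nrow = d[1] * d[2], ncol = d[3])
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  # expand.grid varies row fastest, matching R's column-major flattening
  dt <- data.table::data.table(row = rc$row, col = rc$col)
  for (b in seq_len(d[3])) dt[[sprintf("b%04d", b)]] <- fmt_full(flat[, b])
  data.table::fwrite(dt, path, quote = FALSE)
}

read_value_table <- function(path, nrow_, ncol_, nband) {
  dt <- data.table::fread(path, colClasses = list(character = 3:(nband + 2)))
  stopifnot(nrow(dt) == nrow_ * ncol_)
  vals <- as.matrix(dt[, -(1:2)])
  storage.mode(vals) <- "double"
  arr <- array(NA_real_, dim = c(nrow_, ncol_, nband))
  idx <- cbind(rep(dt$row, nband), rep(dt$col, nband),
               rep(seq_len(nband), each = nrow(dt)))
  arr[idx] <- vals
  arr
}

grid_to_list <- function(grid) if (is.null(grid)) NULL else unclass(grid)
grid_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  grid_geometry(x$xmin, x$ymax, x$xres, x$yres, x$nrow, x$ncol)
}

#' Write an NDVI cube to a plain-text container
#'
#' Persists a cube as a directory: `meta.json` (dimensions, years, composite
#' DOYs, nodata, grid geometry), `values.csv` and `weight.csv` (one pixel per
#' row, one band per column, bands labeled year-major so the (year, DOY)
#' stamp of every band is reconstructible), and `mask.csv`. The write-read
#' round trip preserves values exactly.
#'
#' @param cube An [ndvi_cube()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_ndvi_cube()]
#' @export
write_ndvi_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "ndvi_cube"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(type = "ndvi_cube", nrow = dim(cube$values)[1],
               ncol = dim(cube$values)[2], years = cube$years,
               doys = cube$doys, nodata = cube$nodata,
               grid = grid_to_list(cube$grid))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  vals <- cube$values
  vals[cube$weight == 0L & is.na(vals)] <- cube$nodata
  write_value_table(vals, file.path(dir, "values.csv"))
  write_value_table(cube$weight + 0.0, file.path(dir, "weight.csv"))
  mask <- data.table::data.table(which(cube$mask | TRUE, arr.ind = TRUE))
  data.table::fwrite(
    data.table::data.table(row = mask$row, col = mask$col,
                           mask = as.integer(cube$mask[cbind(mask$row, mask$col)])),
    file.path(dir, "mask.csv"))
  invisible(dir)
}

#' Read an NDVI cube from its plain-text container
#'
#' Inverse of [write_ndvi_cube()]. Band count must be a whole multiple of the
#' per-year composite count; nodata and non-finite values are flagged as
#' weight 0 (a stray `NaN`/`NA` in the value table raises a warning with the
#' number of samples flagged).
#'
#' @param dir Directory written by [write_ndvi_cube()].
#' @return An [ndvi_cube()].
#' @export
read_ndvi_cube <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$type, "ndvi_cube"))
    stop("not an ndvi_cube container", call. = FALSE)
  nband <- length(meta$years) * length(meta$doys)
  values <- read_value_table(file.path(dir, "values.csv"),
                             meta$nrow, meta$ncol, nband)
  if (dim(values)[3] %% length(meta$doys) != 0L)
    stop("band count is not a multiple of the composite count", call. = FALSE)
  weight <- read_value_table(file.path(dir, "weight.csv"),
                             meta$nrow, meta$ncol, nband)
  weight <- array(as.integer(round(weight)), dim = dim(weight))
  stray <- !is.finite(values) & weight == 1L
  nd <- values == meta$nodata & !is.na(values)
  if (any(stray))
    warning(sprintf("%d non-finite valid samples flagged as missing",
                    sum(stray)), call. = FALSE)
  weight[stray | nd] <- 0L
  mdt <- data.table::fread(file.path(dir, "mask.csv"))
  mask <- matrix(FALSE, meta$nrow, meta$ncol)
  mask[cbind(mdt$row, mdt$col)] <- mdt$mask == 1L
  ndvi_cube(values, weight, years = meta$years, doys = meta$doys,
            mask = mask, grid = grid_from_list(meta$grid),
            nodata = meta$nodata)
}

#' Write / read a monthly meteorological cube
#'
#' Same plain-text container scheme as [write_ndvi_cube()], with bands
#' ordered year-major over the 12 months.
#'
#' @param cube A [met_cube()].
#' @param dir Container directory.
#' @return `dir` (write) or a [met_cube()] (read).
#' @export
write_met_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "met_cube"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(cube$values)
  meta <- list(type = "met_cube", nrow = d[1], ncol = d[2],
               years = cube$years, variable = cube$variable,
               grid = grid_to_list(cube$grid))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write_value_table(array(cube$values, dim = c(d[1], d[2], d[3] * 12L)),
                    file.path(dir, "values.csv"))
  invisible(dir)
}

#' @rdname write_met_cube
#' @export
read_met_cube <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$type, "met_cube"))
    stop("not a met_cube container", call. = FALSE)
  ny <- length(meta$years)
  flat <- read_value_table(file.path(dir, "values.csv"),
                           meta$nrow, meta$ncol, ny * 12L)
  met_cube(array(flat, dim = c(meta$nrow, meta$ncol, ny, 12L)),
           years = meta$years, grid = grid_from_list(meta$grid),
           variable = meta$variable)
}

#' Read / write site growth-stage observations
#'
#' CSV with header `site_id, lon, lat, year, stage, observed_doy` (optional
#' `row`, `col` pixel indices; when absent they are derived from lon/lat via
#' the grid at validation time).
#'
#' @param path CSV path.
#' @param sites data.frame of observations.
#' @return data.frame (read) or `path` invisibly (write).
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "stage", "observed_doy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sites CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$stage %in% c("jointing", "tasseling", "maturity")))
    stop("unknown stage names in sites CSV", call. = FALSE)
  df
}

#' @rdname read_sites
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' Write a stage-date raster layer as CSV
#'
#' One CSV per stage and year, as a `nrow x ncol` table of integer DOYs with
#' undetected pixels encoded by the nodata value (-9999 by default).
#'
#' @param doys Numeric matrix of stage DOYs (`NA` = undetected).
#' @param path Output CSV.
#' @param nodata Nodata code (default -9999).
#' @return `path`, invisibly.
#' @export
write_stage_layer <- function(doys, path, nodata = -9999) {
  m <- doys
  m[is.na(m)] <- nodata
  data.table::fwrite(data.table::as.data.table(m), path, col.names = FALSE)
  invisible(path)
}
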