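#' Default pipeline configuration
#'
#' Assembles the run configuration consumed by [run_pipeline()], either
#' programmatically or merged from a YAML file with the same structure.
#' Stage-to-month mapping defaults to jointing/June, tasseling/July,
#' maturity/September; covariates are taken `lag_months` before those.
#' Default DOY class edges are the 16-day windows the stage maps are
#' summarized by (161/177, 201/217, 257/273).
#'
#' @param input Either `list(scene = <synthetic_scene>)` for an in-memory
#'   run, or `list(ndvi_dir =, lst_dir =, precip_dir =, sites_csv =)` paths
#'   of containers written by the io functions (`lst_dir`/`precip_dir`/
#'   `sites_csv` optional).
#' @param output_dir Directory for artifacts; `NULL` = return results only.
#' @param smoothing List: `method` (`"whittaker"`/`"sg"`), `lambda`
#'   (`"auto"` or number), `diff_order`, `half_window`, `poly_order`.
#' @param window A [season_window()].
#' @param amplitude_min Minimum seasonal amplitude, see [extract_stages()].
#' @param stage_months Named list mapping stage to its calendar month.
#' @param lag_months Covariate lag in months (default 1).
#' @param bin_edges Named list of interior DOY edges per stage.
#' @param bin_year Year whose stage maps are binned (default: last).
#' @return A `run_config` list.
#' @export
run_config <- function(input, output_dir = NULL,
                       smoothing = list(), window = season_window(),
                       amplitude_min = 0.2,
                       stage_months = list(jointing = 6L, tasseling = 7L,
                                           maturity = 9L),
                       lag_months = 1L,
                       bin_edges = list(jointing = c(161, 177),
                                        tasseling = c(201, 217),
                                        maturity = c(257, 273)),
                       bin_year = NULL) {
  sm <- utils::modifyList(list(method = "whittaker", lambda = "auto",
                               diff_order = 3L, half_window = 2L,
                               poly_order = 2L), smoothing)
  if (any(unlist(stage_months) < 1L) || any(unlist(stage_months) > 12L))
    stop("stage months must be within 1-12", call. = FALSE)
  structure(list(input = input, output_dir = output_dir, smoothing = sm,
                 window = window, amplitude_min = amplitude_min,
                 stage_months = stage_months, lag_months = as.integer(lag_months),
                 bin_edges = bin_edges, bin_year = bin_year),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()]
#' (`input`, `output_dir`, `smoothing`, `window: [start, end]`, ...).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(input = y$input)
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  if (!is.null(y$smoothing)) args$smoothing <- y$smoothing
  if (!is.null(y$window)) args$window <- season_window(y$window[[1]], y$window[[2]])
  if (!is.null(y$amplitude_min)) args$amplitude_min <- y$amplitude_min
  if (!is.null(y$stage_months)) args$stage_months <- y$stage_months
  if (!is.null(y$lag_months)) args$lag_months <- y$lag_months
  if (!is.null(y$bin_edges)) args$bin_edges <- y$bin_edges
  if (!is.null(y$bin_year)) args$bin_year <- y$bin_year
  do.call(run_config, args)
}

pipeline_inputs <- function(cfg) {
  inp <- cfg$input
  if (!is.null(inp$scene)) {
    sc <- inp$scene
    return(list(ndvi = sc$ndvi, lst = sc$met$lst, precip = sc$met$precip,
                sites = sc$sites))
  }
  if (is.null(inp$ndvi_dir)) stop("no NDVI input configured", call. = FALSE)
  list(ndvi = read_ndvi_cube(inp$ndvi_dir),
       lst = if (!is.null(inp$lst_dir)) read_met_cube(inp$lst_dir),
       precip = if (!is.null(inp$precip_dir)) read_met_cube(inp$precip_dir),
       sites = if (!is.null(inp$sites_csv)) read_sites(inp$sites_csv))
}

#' Run the end-to-end growth-stage pipeline
#'
#' Executes, per masked pixel and year: smoothing, daily spline
#' interpolation and stage extraction; then the map-level analytics —
#' interannual trend of each stage (days/year with significance), Pearson
#' correlation of each stage against the preceding-month temperature and
#' precipitation covariates, the dominant-factor map, DOY-bin area
#' fractions, and RMSE/MAE/MAPE validation against the site observations.
#' The run is fully deterministic for fixed inputs and configuration. When
#' `output_dir` is set, stage layers (CSV, nodata -9999), trend/correlation
#' tables, bin summaries, the validation report and a `summary.json`
#' manifest are written there.
#'
#' @param cfg A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return A list of class `pipeline_result` with elements `stages`
#'   (a `stage_maps` list), `trends`, `correlations`, `dominant`, `bins`,
#'   `validation`, `summary`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  io <- pipeline_inputs(cfg)
  cube <- io$ndvi
  if (!any(cube$mask)) stop("empty mask: no pixels to process", call. = FALSE)
  sm <- cfg$smoothing
  stages <- extract_stage_maps(cube, method = sm$method, window = cfg$window,
                               amplitude_min = cfg$amplitude_min,
                               lambda = sm$lambda, diff_order = sm$diff_order,
                               half_window = sm$half_window,
                               poly_order = sm$poly_order)
  stage_names <- c("jointing", "tasseling", "maturity")

  trends <- lapply(stage_names, function(s)
    stage_trend_map(stages[[s]], cube$years))
  names(trends) <- stage_names

  correlations <- list()
  dominant <- list()
  for (s in stage_names) {
    month_s <- cfg$stage_months[[s]]
    ct <- if (!is.null(io$lst))
      correlate_stage_met(stages[[s]], cube$years, io$lst, month_s,
                          cfg$lag_months)
    cp <- if (!is.null(io$precip))
      correlate_stage_met(stages[[s]], cube$years, io$precip, month_s,
                          cfg$lag_months)
    correlations[[s]] <- list(lst = ct, precip = cp)
    if (!is.null(ct) && !is.null(cp))
      dominant[[s]] <- dominant_factor(ct$r, cp$r, mask = cube$mask)
  }

  bin_year <- if (is.null(cfg$bin_year)) max(cube$years) else cfg$bin_year
  byi <- match(bin_year, cube$years)
  bins <- lapply(stage_names, function(s)
    tryCatch(doy_bin_summary(stages[[s]][, , byi], cfg$bin_edges[[s]],
                             mask = cube$mask),
             error = function(e) NULL))
  names(bins) <- stage_names

  validation <- if (!is.null(io$sites))
    validate_against_sites(stages, io$sites, cube$grid)

  summary <- list(
    n_pixels = sum(cube$mask), years = cube$years,
    smoothing = sm[c("method", "lambda", "diff_order")],
    detected_fraction = vapply(stage_names, function(s)
      mean(!is.na(stages[[s]][rep_len(cube$mask, length(stages[[s]]))])),
      numeric(1)),
    mean_doy = vapply(stage_names, function(s)
      mean(stages[[s]], na.rm = TRUE), numeric(1)),
    mean_trend = vapply(stage_names, function(s)
      mean(trends[[s]]$slope_b, na.rm = TRUE), numeric(1)),
    advancing_fraction = vapply(stage_names, function(s)
      mean(trends[[s]]$slope_b < 0, na.rm = TRUE), numeric(1)))

  res <- structure(list(stages = stages, trends = trends,
                        correlations = correlations, dominant = dominant,
                        bins = bins, validation = validation,
                        summary = summary, config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$output_dir)) write_pipeline_outputs(res, cfg$output_dir)
  res
}

#' Validate stage maps against site observations
#'
#' Matches each site observation to its pixel (by `row`/`col` when present,
#' otherwise by lon/lat through the grid geometry) and year, and computes
#' RMSE, MAE and MAPE of extracted versus observed DOYs per stage. Sites
#' whose pixel-year is undetected are dropped from the metrics.
#'
#' @param stages A `stage_maps` list from [extract_stage_maps()].
#' @param sites data.frame as from [read_sites()].
#' @param grid [grid_geometry()] for lon/lat matching (optional if `row`,
#'   `col` columns are present).
#' @return data.frame of per-stage `rmse`, `mae`, `mape`, `n` (plus a pooled
#'   `"all"` row), with attribute `"pairs"` holding the matched pairs.
#' @export
validate_against_sites <- function(stages, sites, grid = NULL) {
  if (is.null(sites$row) || is.null(sites$col)) {
    if (is.null(grid))
      stop("sites lack row/col and no grid is available for lon/lat lookup",
           call. = FALSE)
    loc <- grid_locate(grid, sites$lon, sites$lat)
    sites$row <- loc$row; sites$col <- loc$col
  }
  yidx <- match(sites$year, stages$years)
  extracted <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (is.na(yidx[i]) || is.na(sites$row[i])) next
    extracted[i] <- stages[[sites$stage[i]]][sites$row[i], sites$col[i], yidx[i]]
  }
  ok <- !is.na(extracted)
  pairs <- data.frame(sites[ok, c("site_id", "year", "stage", "observed_doy")],
                      extracted_doy = extracted[ok])
  per_stage <- lapply(split(pairs, pairs$stage), function(p)
    validation_metrics(p$extracted_doy, p$observed_doy, stage = p$stage[1]))
  rows <- lapply(per_stage, function(v)
    data.frame(stage = v$stage, rmse = v$rmse, mae = v$mae, mape = v$mape,
               n = v$n, stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(local({
    v <- validation_metrics(pairs$extracted_doy, pairs$observed_doy, "all")
    data.frame(stage = "all", rmse = v$rmse, mae = v$mae, mape = v$mape,
               n = v$n, stringsAsFactors = FALSE)
  }))))
  rownames(out) <- NULL
  attr(out, "pairs") <- pairs
  out
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- res$stages
  for (s in c("jointing", "tasseling", "maturity")) {
    sd <- file.path(dir, "stages", s)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    for (yi in seq_along(st$years))
      write_stage_layer(st[[s]][, , yi],
                        file.path(sd, sprintf("%s_%d.csv", s, st$years[yi])))
    tr <- res$trends[[s]]
    data.table::fwrite(pixel_corr_table(tr),
                       file.path(dir, sprintf("trend_%s.csv", s)))
    for (v in c("lst", "precip")) {
      cr <- res$correlations[[s]][[v]]
      if (!is.null(cr))
        data.table::fwrite(pixel_corr_table(cr),
                           file.path(dir, sprintf("corr_%s_%s.csv", s, v)))
    }
    if (!is.null(res$dominant[[s]]))
      data.table::fwrite(res$dominant[[s]]$fractions,
                         file.path(dir, sprintf("dominant_%s.csv", s)))
    if (!is.null(res$bins[[s]]))
      data.table::fwrite(res$bins[[s]],
                         file.path(dir, sprintf("bins_%s.csv", s)))
  }
  if (!is.null(res$validation))
    data.table::fwrite(res$validation, file.path(dir, "validation.csv"))
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

pixel_corr_table <- function(pc) {
  d <- dim(pc$r)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  data.frame(row = rc$row, col = rc$col,
             slope_b = as.vector(pc$slope_b), r = as.vector(pc$r),
             p_value = as.vector(pc$p_value), n_used = as.vector(pc$n_used),
             significance = as.vector(pc$significance),
             stringsAsFactors = FALSE)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_result> %d pixels, years %d-%d, %s smoothing\n",
              s$n_pixels, min(s$years), max(s$years), s$smoothing$method))
  cat(sprintf("  mean DOY: jointing %.1f, tasseling %.1f, maturity %.1f\n",
              s$mean_doy[1], s$mean_doy[2], s$mean_doy[3]))
  cat(sprintf("  mean trend (d/yr): %.2f / %.2f / %.2f\n",
              s$mean_trend[1], s$mean_trend[2], s$mean_trend[3]))
  if (!is.null(x$validation)) {
    v <- x$validation[x$validation$stage == "all", ]
    cat(sprintf("  validation (n=%d): RMSE %.2f d, MAE %.2f d, MAPE %.2f%%\n",
                v$n, v$rmse, v$mae, v$mape))
  }
  invisible(x)
}
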