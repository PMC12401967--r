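#' Season window for stage detection
#'
#' DOY window inside which stages are sought. The default 97-297 matches a
#' 26-composite April-to-October record at an 8-day step.
#'
#' @param start_doy First DOY of the window (default 97).
#' @param end_doy Last DOY of the window (default 297).
#' @return A `season_window` list.
#' @export
season_window <- function(start_doy = 97L, end_doy = 297L) {
  start_doy <- as.integer(start_doy); end_doy <- as.integer(end_doy)
  if (start_doy >= end_doy)
    stop("`start_doy` must be earlier than `end_doy`", call. = FALSE)
  structure(list(start_doy = start_doy, end_doy = end_doy),
            class = "season_window")
}

# restrict a daily curve to the part of the window it covers
window_indices <- function(curve, window) {
  lo <- max(window$start_doy, min(curve$doy))
  hi <- min(window$end_doy, max(curve$doy))
  if (lo >= hi) stop("curve does not cover the season window", call. = FALSE)
  which(curve$doy >= lo & curve$doy <= hi)
}

undetected <- function(flag) list(doy = NA_integer_, flag = flag)

# drop leading/trailing cloud-flagged composites: the smoothers would have to
# extrapolate there (the d=3 Whittaker penalty continues the last quadratic),
# and a fabricated steep tail routinely masquerades as the senescence
# inflection. Interior gaps keep their support and are interpolated.
trim_invalid_ends <- function(series) {
  w <- series$weight
  ok <- which(w == 1L)
  lo <- ok[1]; hi <- ok[length(ok)]
  if (lo == 1L && hi == length(w)) return(series)
  idx <- lo:hi
  ndvi_series(series$doy[idx], series$value[idx], w[idx], year = series$year)
}

#' Detect the tasseling stage (curve peak, zero slope)
#'
#' The tasseling date is the DOY of the seasonal curve's maximum within the
#' window — the zero-slope point where NDVI-proxied biomass peaks. The maximum
#' must be an interior peak (rising slope somewhere before it, falling slope
#' somewhere after); a maximum sitting on a window boundary is reported as
#' undetected with flag `edge_peak`. Ties break to the earliest DOY.
#'
#' @param curve A [spline_daily()] curve covering the window.
#' @param window A [season_window()].
#' @return List with `doy` (integer DOY or `NA`) and `flag`
#'   (`"ok"` or `"edge_peak"`).
#' @export
detect_tasseling <- function(curve, window = season_window()) {
  idx <- window_indices(curve, window)
  days <- curve$doy[idx]
  vals <- curve$value[idx]
  i <- which.max(vals)                       # which.max returns the first tie
  peak <- days[i]
  if (i == 1L || i == length(idx)) return(undetected("edge_peak"))
  before <- curve$deriv[idx[seq_len(i)]]
  after <- curve$deriv[idx[i:length(idx)]]
  if (max(before) <= 0 || min(after) >= 0) return(undetected("edge_peak"))
  list(doy = as.integer(peak), flag = "ok")
}

#' Detect the jointing stage (maximum positive slope before the peak)
#'
#' The jointing date is the DOY of the strongest positive slope of the
#' seasonal curve on `[window start, tasseling)` — the rising inflection
#' marking the most rapid vegetative growth. The slope maximum must be an
#' interior local maximum of the derivative (an actual inflection): a
#' derivative that keeps growing right up to the boundary of the search
#' interval is a fit artifact, not a green-up feature, and the best interior
#' local maximum is used instead. Undetected with `no_peak` if the curve
#' never rises, with `edge_peak` if the slope has no interior local maximum.
#' Ties break to the earliest DOY.
#'
#' @param curve A [spline_daily()] curve.
#' @param tasseling Detected tasseling DOY.
#' @param window A [season_window()].
#' @return List with `doy` and `flag` (`"ok"`, `"no_peak"` or `"edge_peak"`).
#' @export
detect_jointing <- function(curve, tasseling, window = season_window()) {
  idx <- window_indices(curve, window)
  idx <- idx[curve$doy[idx] < tasseling]
  if (length(idx) == 0L) return(undetected("no_peak"))
  d <- curve$deriv[idx]
  if (max(d) <= 0) return(undetected("no_peak"))
  i <- interior_extremum(d, decreasing = TRUE)
  if (is.na(i)) return(undetected("edge_peak"))
  list(doy = as.integer(curve$doy[idx[i]]), flag = "ok")
}

#' Detect the maturity stage (maximum negative slope after the peak)
#'
#' The maturity date is the DOY of the strongest negative slope on
#' `(tasseling, window end]` — the falling inflection marking the fastest
#' senescence. As for jointing, the slope minimum must be an interior local
#' minimum of the derivative: smoothed declines often steepen all the way to
#' the end of the observed record, and that boundary slope reflects the
#' fitted tail rather than a senescence inflection. Undetected with
#' `no_peak` if the curve never declines, with `edge_peak` if the slope has
#' no interior local minimum. Ties break to the earliest DOY.
#'
#' @inheritParams detect_jointing
#' @return List with `doy` and `flag` (`"ok"`, `"no_peak"` or `"edge_peak"`).
#' @export
detect_maturity <- function(curve, tasseling, window = season_window()) {
  idx <- window_indices(curve, window)
  idx <- idx[curve$doy[idx] > tasseling]
  if (length(idx) == 0L) return(undetected("no_peak"))
  d <- curve$deriv[idx]
  if (min(d) >= 0) return(undetected("no_peak"))
  i <- interior_extremum(-d, decreasing = TRUE)
  if (is.na(i) || d[i] >= 0) return(undetected("edge_peak"))
  list(doy = as.integer(curve$doy[idx[i]]), flag = "ok")
}

# index of the best interior local maximum of v (weak local maxima qualify,
# so a flat plateau of the derivative counts and resolves to its earliest
# day); NA when v is monotone up to the interval boundary
interior_extremum <- function(v, decreasing = TRUE) {
  n <- length(v)
  if (n < 3L) return(NA_integer_)
  i <- 2:(n - 1L)
  loc <- i[v[i] >= v[i - 1L] & v[i] >= v[i + 1L]]
  if (length(loc) == 0L) return(NA_integer_)
  loc[which.max(v[loc])]
}

#' Extract the three maize growth stages from one composite series
#'
#' End-to-end slope-feature-node extraction for a single pixel-year: smooth
#' the composites (Whittaker or Savitzky-Golay), interpolate to a daily curve
#' by natural cubic spline, then locate tasseling (peak), jointing (maximum
#' positive slope before the peak) and maturity (maximum negative slope after
#' it). Series whose smoothed seasonal amplitude within the window is below
#' `amplitude_min` (bare soil, failed pixels) are rejected with flag
#' `low_amplitude`.
#'
#' @param series An [ndvi_series()].
#' @param method `"whittaker"` (default) or `"sg"`.
#' @param window A [season_window()].
#' @param amplitude_min Minimum max-min smoothed NDVI within the window
#'   (default 0.2).
#' @param lambda,diff_order,lambda_grid Whittaker settings, see
#'   [whittaker_smooth()].
#' @param half_window,poly_order Savitzky-Golay settings, see [sg_smooth()].
#' @return An object of class `stage_dates`: list with integer DOYs
#'   `jointing`, `tasseling`, `maturity` (`NA` when undetected) and
#'   `quality_flag` in `ok`, `low_amplitude`, `no_peak`, `edge_peak`.
#' @examples
#' doys <- seq(97, 297, by = 8)
#' s <- ndvi_series(doys, double_logistic(doys))
#' extract_stages(s, lambda = 10)
#' @export
extract_stages <- function(series, method = c("whittaker", "sg"),
                           window = season_window(), amplitude_min = 0.2,
                           lambda = "auto", diff_order = 3L,
                           lambda_grid = 10^seq(-1, 4, length.out = 13),
                           half_window = 2L, poly_order = 2L) {
  stopifnot(inherits(series, "ndvi_series"))
  method <- match.arg(method)
  if (all(series$weight == 0L))
    stop("degenerate series: all samples flagged invalid", call. = FALSE)
  series <- trim_invalid_ends(series)
  sm <- switch(method,
               whittaker = whittaker_smooth(series, lambda = lambda,
                                            diff_order = diff_order,
                                            lambda_grid = lambda_grid),
               sg = sg_smooth(series, half_window = half_window,
                              poly_order = poly_order))
  curve <- spline_daily(sm)
  idx <- window_indices(curve, window)
  amp <- diff(range(curve$value[idx]))
  if (amp < amplitude_min)
    return(stage_dates(NA, NA, NA, "low_amplitude"))
  tas <- detect_tasseling(curve, window)
  if (is.na(tas$doy))
    return(stage_dates(NA, NA, NA, tas$flag))
  joi <- detect_jointing(curve, tas$doy, window)
  mat <- detect_maturity(curve, tas$doy, window)
  flag <- if (is.na(joi$doy) || is.na(mat$doy)) "no_peak" else "ok"
  stage_dates(joi$doy, tas$doy, mat$doy, flag)
}

stage_dates <- function(jointing, tasseling, maturity, quality_flag) {
  structure(list(jointing = as.integer(jointing),
                 tasseling = as.integer(tasseling),
                 maturity = as.integer(maturity),
                 quality_flag = quality_flag),
            class = "stage_dates")
}

#' @export
print.stage_dates <- function(x, ...) {
  fmt <- function(d) if (is.na(d)) "--" else as.character(d)
  cat(sprintf("<stage_dates> jointing %s, tasseling %s, maturity %s [%s]\n",
              fmt(x$jointing), fmt(x$tasseling), fmt(x$maturity),
              x$quality_flag))
  invisible(x)
}
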