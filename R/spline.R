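#' Upsample a smoothed composite series to a daily curve
#'
#' Fits the natural cubic spline through the smoothed composite values (zero
#' second derivative at the season edges; no derivative information is
#' available there) and evaluates it, together with its analytic first
#' derivative, at every integer DOY from the first to the last knot. The
#' analytic derivative — not a finite difference of the daily values — is what
#' the stage detectors consume, which avoids quantization noise at the
#' 1-day grid. No extrapolation outside the knot range.
#'
#' @param series A `smoothed_series` (or any list with numeric `doy`, `value`),
#'   at least 4 samples, strictly increasing `doy`.
#' @return An object of class `daily_curve`: list with `doy` (integer daily
#'   grid), `value`, `deriv` (NDVI/day), and `spline` (the underlying
#'   `splinefun` for exact evaluation at arbitrary DOY).
#' @examples
#' s <- ndvi_series(seq(97, 297, by = 8),
#'                  double_logistic(seq(97, 297, by = 8)))
#' curve <- spline_daily(sg_smooth(s))
#' range(curve$doy)
#' @export
spline_daily <- function(series) {
  doy <- series$doy
  value <- series$value
  if (length(doy) < 4L)
    stop("need at least 4 samples for cubic-spline interpolation",
         call. = FALSE)
  if (any(diff(doy) <= 0))
    stop("`doy` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(value)))
    stop("spline input values must be finite", call. = FALSE)
  f <- stats::splinefun(doy, value, method = "natural")
  days <- seq.int(min(doy), max(doy))
  structure(list(doy = days,
                 value = f(days),
                 deriv = f(days, deriv = 1),
                 spline = f),
            class = "daily_curve")
}

#' @export
print.daily_curve <- function(x, ...) {
  cat(sprintf("<daily_curve> DOY %d-%d (%d days), NDVI range [%.3f, %.3f]\n",
              min(x$doy), max(x$doy), length(x$doy),
              min(x$value), max(x$value)))
  invisible(x)
}
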