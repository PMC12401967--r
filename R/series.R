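#' NDVI composite series for one pixel-year
#'
#' Container for a single pixel-year of NDVI composites on a uniform DOY grid
#' (8-day step for MODIS-style products, 26 composites covering April to
#' October). Each sample carries a validity weight: 0 marks a cloud-flagged or
#' missing composite whose value should not constrain the smoothers.
#'
#' @param doy Integer days of year of the composites, strictly increasing with
#'   a uniform step.
#' @param value NDVI values, dimensionless in \eqn{[-1, 1]} where valid.
#' @param weight Per-sample validity in \{0, 1\} (0 = cloud/missing). Defaults
#'   to all valid.
#' @param year Calendar year the series belongs to (optional bookkeeping).
#' @return An object of class `ndvi_series`: a list with elements `doy`,
#'   `value`, `weight`, `year`.
#' @examples
#' s <- ndvi_series(doy = seq(97, 297, by = 8),
#'                  value = 0.2 + 0.5 * sin(seq(0, pi, length.out = 26)))
#' s
#' @export
ndvi_series <- function(doy, value, weight = NULL, year = NA_integer_) {
  doy <- as.integer(doy)
  n <- length(doy)
  if (length(value) != n)
    stop("`doy` and `value` must have the same length", call. = FALSE)
  if (is.null(weight)) weight <- rep(1L, n)
  if (length(weight) != n)
    stop("`weight` must match `doy` in length", call. = FALSE)
  weight <- as.integer(weight)
  if (anyNA(weight) || !all(weight %in% c(0L, 1L)))
    stop("`weight` must contain only 0 or 1", call. = FALSE)
  if (n >= 2L) {
    steps <- diff(doy)
    if (any(steps <= 0L))
      stop("`doy` must be strictly increasing", call. = FALSE)
    if (length(unique(steps)) != 1L)
      stop("`doy` must be uniformly spaced", call. = FALSE)
  }
  value <- as.numeric(value)
  v <- value[weight == 1L]
  if (any(!is.finite(v)) || any(v < -1 | v > 1))
    stop("valid NDVI values must be finite and within [-1, 1]", call. = FALSE)
  structure(list(doy = doy, value = value, weight = weight,
                 year = as.integer(year)[1L]),
            class = "ndvi_series")
}

#' @export
print.ndvi_series <- function(x, ...) {
  cat(sprintf("<ndvi_series> %d composites, DOY %d-%d (step %d), %d flagged%s\n",
              length(x$doy), min(x$doy), max(x$doy),
              if (length(x$doy) > 1) diff(x$doy)[1] else 0L,
              sum(x$weight == 0L),
              if (is.na(x$year)) "" else sprintf(", year %d", x$year)))
  invisible(x)
}

#' @export
length.ndvi_series <- function(x) length(x$doy)

# internal constructor for smoother output; keeps the input DOY grid and
# records which method and resolved configuration produced it
smoothed_series <- function(doy, value, method, config) {
  stopifnot(length(doy) == length(value), all(is.finite(value)))
  structure(list(doy = as.integer(doy), value = as.numeric(value),
                 method = method, config = config),
            class = "smoothed_series")
}

#' @export
print.smoothed_series <- function(x, ...) {
  cat(sprintf("<smoothed_series> method '%s', %d samples, DOY %d-%d\n",
              x$method, length(x$doy), min(x$doy), max(x$doy)))
  invisible(x)
}

# linear gap-fill of weight-0 samples from nearest valid neighbours;
# edge gaps take the nearest valid value (rule = 2)
gap_fill_values <- function(series) {
  w <- series$weight
  if (all(w == 0L))
    stop("degenerate series: no valid samples to gap-fill", call. = FALSE)
  if (all(w == 1L)) return(series$value)
  ok <- which(w == 1L)
  if (length(ok) == 1L) return(rep(series$value[ok], length(w)))
  stats::approx(x = series$doy[ok], y = series$value[ok],
                xout = series$doy, method = "linear", rule = 2)$y
}
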