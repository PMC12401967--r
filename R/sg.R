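#' Savitzky-Golay convolution weights
#'
#' Weights of the Savitzky-Golay moving-window least-squares filter: applying
#' them to a window of 2m+1 equally spaced samples gives the value at the
#' window centre of the least-squares polynomial fit of the requested order.
#' The weights sum to 1 and are symmetric about the centre.
#'
#' @param half_window Integer m >= 1; the window holds 2m+1 samples.
#' @param poly_order Integer polynomial order, 0 <= order < 2m+1.
#' @return Numeric weight vector of length 2m+1.
#' @examples
#' sg_coefficients(2, 2)           # the classic (-3, 12, 17, 12, -3)/35
#' sg_coefficients(2, 0)           # order 0 reduces to a moving average
#' @export
sg_coefficients <- function(half_window, poly_order) {
  m <- as.integer(half_window)
  p <- as.integer(poly_order)
  if (is.na(m) || m < 1L)
    stop("`half_window` must be an integer >= 1", call. = FALSE)
  if (is.na(p) || p < 0L || p >= 2L * m + 1L)
    stop("`poly_order` must satisfy 0 <= order < 2*half_window + 1",
         call. = FALSE)
  x <- seq.int(-m, m)
  V <- outer(x, 0:p, `^`)
  # fitted value at the centre is v_c' (V'V)^-1 V' y, i.e. a fixed row of the
  # hat matrix: weights_i = v_i' (V'V)^-1 v_c
  vc <- V[m + 1L, ]
  as.numeric(V %*% solve(crossprod(V), vc))
}

#' Smooth an NDVI series with the Savitzky-Golay filter
#'
#' Moving-window least-squares polynomial smoothing. Weight-0 (cloud/missing)
#' samples are first linearly gap-filled from their nearest valid neighbours,
#' since the convolution assumes a uniformly valid grid; the ends of the
#' series are mirror-padded by m samples so the output keeps the input length
#' without shrinking the window at the season boundaries.
#'
#' @param series An [ndvi_series()].
#' @param half_window Integer m; window of 2m+1 composites (default 2, i.e. a
#'   5-composite / 40-day window).
#' @param poly_order Polynomial order of the local fit (default 2).
#' @return A `smoothed_series` on the same DOY grid, `method = "sg"`.
#' @seealso [whittaker_smooth()]
#' @export
sg_smooth <- function(series, half_window = 2L, poly_order = 2L) {
  stopifnot(inherits(series, "ndvi_series"))
  m <- as.integer(half_window)
  n <- length(series$doy)
  if (n < 2L * m + 1L)
    stop("series shorter than the smoothing window", call. = FALSE)
  w <- sg_coefficients(m, poly_order)
  y <- gap_fill_values(series)
  ypad <- c(y[(m + 1L):2L], y, y[(n - 1L):(n - m)])
  # symmetric kernel, so convolution orientation is immaterial
  sm <- as.numeric(stats::filter(ypad, w, method = "convolution", sides = 2))
  sm <- sm[(m + 1L):(m + n)]
  smoothed_series(series$doy, sm, "sg",
                  list(half_window = m, poly_order = as.integer(poly_order)))
}
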