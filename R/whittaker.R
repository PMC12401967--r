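#' Whittaker smoother objective: fidelity, roughness and their balance
#'
#' Decomposes the penalized-least-squares objective of the Whittaker smoother
#' for a candidate smooth sequence z: the fidelity
#' \eqn{S = \sum_i w_i (y_i - z_i)^2}, the roughness
#' \eqn{R = \sum_i (\Delta^d z_i)^2} (squared d-th order differences; d = 3 is
#' the default here, penalizing departures from a local quadratic), and the
#' objective \eqn{Q = S + \lambda R}.
#'
#' @param y An [ndvi_series()] (its weights enter S) or a plain numeric
#'   vector (unit weights).
#' @param z Candidate smoothed values, same length as `y`.
#' @param lambda Smoothing parameter \eqn{\lambda \ge 0}.
#' @param diff_order Difference order d >= 1 of the roughness penalty.
#' @return A list with components `Q`, `S`, `R`.
#' @export
whittaker_objective <- function(y, z, lambda, diff_order = 3L) {
  if (inherits(y, "ndvi_series")) {
    w <- as.numeric(y$weight)
    yv <- ifelse(y$weight == 1L, y$value, 0)
  } else {
    w <- rep(1, length(y))
    yv <- as.numeric(y)
  }
  if (length(z) != length(yv))
    stop("`y` and `z` must have the same length", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  S <- sum(w * (yv - z)^2)
  R <- sum(diff(z, differences = as.integer(diff_order))^2)
  list(Q = S + lambda * R, S = S, R = R)
}

# d-th order difference matrix, (n-d) x n
difference_matrix <- function(n, d) {
  diff(diag(n), differences = as.integer(d))
}

# core penalized least-squares solve: (W + lambda D'D) z = W y
whittaker_solve <- function(y, w, lambda, diff_order) {
  n <- length(y)
  D <- difference_matrix(n, diff_order)
  A <- diag(w, n) + lambda * crossprod(D)
  yv <- ifelse(w > 0, y, 0)
  z <- tryCatch(solve(A, w * yv),
                error = function(e)
                  stop("degenerate Whittaker system (singular normal equations): ",
                       conditionMessage(e), call. = FALSE))
  as.numeric(z)
}

#' Smooth an NDVI series with the Whittaker filter
#'
#' Penalized least squares: finds the sequence z minimizing
#' \eqn{Q = \sum_i w_i (y_i - z_i)^2 + \lambda \sum (\Delta^d z)^2} via the
#' banded normal equations \eqn{(W + \lambda D^T D) z = W y}. Cloud-flagged
#' samples (weight 0) carry no fidelity weight and are effectively
#' interpolated by the penalty. With `lambda = "auto"` the smoothing
#' parameter is chosen by leave-one-out cross-validation over `lambda_grid`
#' (see [select_lambda()]).
#'
#' @param series An [ndvi_series()].
#' @param lambda Positive smoothing parameter, 0 for no smoothing, or
#'   `"auto"` for LOO-CV selection (the default).
#' @param diff_order Difference order d of the penalty (default 3).
#' @param lambda_grid Candidate \eqn{\lambda} values for `"auto"`; defaults to
#'   13 log-spaced points over \eqn{10^{-1} \ldots 10^{4}}.
#' @return A `smoothed_series` on the same DOY grid, `method = "whittaker"`;
#'   `config$lambda` records the resolved value.
#' @seealso [sg_smooth()], [whittaker_objective()]
#' @export
whittaker_smooth <- function(series, lambda = "auto", diff_order = 3L,
                             lambda_grid = 10^seq(-1, 4, length.out = 13)) {
  stopifnot(inherits(series, "ndvi_series"))
  d <- as.integer(diff_order)
  n <- length(series$doy)
  if (d < 1L || d > n - 1L)
    stop("`diff_order` must be >= 1 and <= length(series) - 1", call. = FALSE)
  if (all(series$weight == 0L))
    stop("degenerate series: all samples flagged invalid", call. = FALSE)
  if (identical(lambda, "auto"))
    lambda <- select_lambda(series, lambda_grid, d)
  lambda <- as.numeric(lambda)
  if (is.na(lambda) || lambda < 0)
    stop("`lambda` must be >= 0 or \"auto\"", call. = FALSE)
  z <- whittaker_solve(series$value, as.numeric(series$weight), lambda, d)
  smoothed_series(series$doy, z, "whittaker",
                  list(lambda = lambda, diff_order = d))
}

#' Select the Whittaker smoothing parameter by leave-one-out cross-validation
#'
#' Scores each candidate \eqn{\lambda} by the mean squared leave-one-out
#' residual over the valid samples and returns the minimizer (ties broken
#' toward the smallest \eqn{\lambda}, preferring fidelity when the CV curve is
#' flat). Because the smoother is linear in the data, the LOO residual is
#' computed exactly from a single fit through the leverage identity
#' \eqn{e_i^{loo} = (y_i - z_i) / (1 - h_{ii})} with
#' \eqn{H = (W + \lambda D^T D)^{-1} W}.
#'
#' @param series An [ndvi_series()] with at least `diff_order + 2` valid
#'   samples.
#' @param lambda_grid Non-empty vector of candidate \eqn{\lambda > 0}.
#' @param diff_order Difference order of the penalty (default 3).
#' @return The selected \eqn{\lambda} (an element of `lambda_grid`).
#' @export
select_lambda <- function(series,
                          lambda_grid = 10^seq(-1, 4, length.out = 13),
                          diff_order = 3L) {
  stopifnot(inherits(series, "ndvi_series"))
  if (length(lambda_grid) == 0L)
    stop("`lambda_grid` must be non-empty", call. = FALSE)
  if (any(!is.finite(lambda_grid)) || any(lambda_grid <= 0))
    stop("all candidate lambda values must be finite and > 0", call. = FALSE)
  d <- as.integer(diff_order)
  w <- as.numeric(series$weight)
  valid <- which(w == 1)
  if (length(valid) < d + 2L)
    stop("need at least diff_order + 2 valid samples for selection",
         call. = FALSE)
  grid <- sort(unique(as.numeric(lambda_grid)))
  y <- ifelse(w > 0, series$value, 0)
  n <- length(y)
  DtD <- crossprod(difference_matrix(n, d))
  cv <- vapply(grid, function(lam) {
    A <- diag(w, n) + lam * DtD
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) return(Inf)
    z <- as.numeric(Ainv %*% (w * y))
    h <- diag(Ainv) * w
    denom <- 1 - h[valid]
    if (any(denom < 1e-10)) return(Inf)
    mean(((y[valid] - z[valid]) / denom)^2)
  }, numeric(1))
  if (all(!is.finite(cv)))
    stop("cross-validation failed for every candidate lambda", call. = FALSE)
  grid[which.min(cv)]
}
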