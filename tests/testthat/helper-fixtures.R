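# shared fixtures and independent oracles for the smoothing / phenology tests

doys8 <- function() seq(97L, 297L, by = 8L)

# one pixel-year of double-logistic composites, optionally noisy
dl_series <- function(noise_sd = 0, seed = NULL, weight = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  v <- double_logistic(doys8(), ...)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  ndvi_series(doys8(), pmin(pmax(v, -1), 1), weight)
}

# dense-matrix Whittaker oracle: straightforward solve of the normal equations
whittaker_dense_oracle <- function(y, w, lambda, d) {
  n <- length(y)
  D <- diff(diag(n), differences = d)
  as.numeric(solve(diag(w, n) + lambda * crossprod(D),
                   w * ifelse(w > 0, y, 0)))
}

# brute-force SG oracle: per-window least-squares polynomial fit evaluated at
# the window centre (mirror padding to match the filter)
sg_window_oracle <- function(y, m, p) {
  n <- length(y)
  ypad <- c(y[(m + 1):2], y, y[(n - 1):(n - m)])
  vapply(seq_len(n), function(j) {
    win <- ypad[j:(j + 2 * m)]
    x <- seq(-m, m)
    if (p == 0) return(mean(win))
    fit <- stats::lm(win ~ stats::poly(x, degree = p, raw = TRUE))
    unname(stats::predict(fit, newdata = data.frame(x = 0)))
  }, numeric(1))
}

# explicit n-refit leave-one-out error of the Whittaker smoother
loo_refit_oracle <- function(series, lambda, d = 3L) {
  valid <- which(series$weight == 1L)
  errs <- vapply(valid, function(i) {
    w2 <- series$weight
    w2[i] <- 0L
    s2 <- ndvi_series(series$doy, series$value, w2)
    z <- whittaker_smooth(s2, lambda = lambda, diff_order = d)$value
    series$value[i] - z[i]
  }, numeric(1))
  mean(errs^2)
}

# fine-grid stage-date oracle evaluated directly on the analytic curve
fine_grid_stages <- function(..., from = 97, to = 297, step = 0.01) {
  g <- seq(from, to, by = step)
  v <- double_logistic(g, ...)
  d <- double_logistic(g, ..., deriv = TRUE)
  tas <- g[which.max(v)]
  c(jointing = g[g < tas][which.max(d[g < tas])],
    tasseling = tas,
    maturity = g[g > tas][which.min(d[g > tas])])
}
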