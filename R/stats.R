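#' Pearson correlation between two annual series
#'
#' Correlation between, e.g., a growth-stage DOY series and a meteorological
#' covariate over years. Missing years are removed by pairwise-complete
#' deletion; at least 3 complete pairs and non-zero variance on both sides are
#' required.
#'
#' @param x,y Numeric vectors of equal length (per-year values; `NA` =
#'   missing year).
#' @return The correlation coefficient in \eqn{[-1, 1]}.
#' @export
pearson_r <- function(x, y) {
  p <- complete_pairs(x, y)
  if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(p$x, p$y)
}

complete_pairs <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  list(x = as.numeric(x[ok]), y = as.numeric(y[ok]), n = sum(ok))
}

#' Interannual trend slope (ordinary least squares)
#'
#' OLS slope of `y` on `x`, \eqn{b = \sum (x_i - \bar x)(y_i - \bar y) /
#' \sum (x_i - \bar x)^2}. With `x` = year and `y` = stage DOY, `b` is in
#' days/year: negative means the stage has advanced, positive that it has
#' been delayed. Missing years are dropped pairwise.
#'
#' @inheritParams pearson_r
#' @return The slope `b`.
#' @export
trend_slope <- function(x, y) {
  p <- complete_pairs(x, y)
  dx <- p$x - mean(p$x)
  if (all(dx == 0)) stop("zero variance in `x`", call. = FALSE)
  sum(dx * (p$y - mean(p$y))) / sum(dx^2)
}

#' Significance of a correlation coefficient (t-test)
#'
#' Two-sided t-test of r against zero: \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with
#' n-2 degrees of freedom. Classified `p01` if p < 0.01 (extremely
#' significant), `p05` if p < 0.05 (significant), else `ns`. \eqn{|r| = 1}
#' gives p = 0 by convention.
#'
#' @param r Correlation coefficient.
#' @param n Number of pairs (>= 3).
#' @return List with `p_value` and `significance` (`"p01"`, `"p05"`, `"ns"`).
#' @export
t_test_r <- function(r, n) {
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (abs(r) > 1 + 1e-12) stop("|r| must be <= 1", call. = FALSE)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  sig <- if (p < 0.01) "p01" else if (p < 0.05) "p05" else "ns"
  list(p_value = p, significance = sig)
}

#' Correlation, slope and significance of an annual series pair
#'
#' Convenience wrapper bundling [pearson_r()], [trend_slope()] and
#' [t_test_r()] with pairwise-complete deletion of missing years.
#'
#' @inheritParams pearson_r
#' @return A `trend_result` list: `slope_b`, `r`, `p_value`, `n_used`,
#'   `significance`.
#' @export
trend_result <- function(x, y) {
  p <- complete_pairs(x, y)
  r <- pearson_r(x, y)
  tt <- t_test_r(r, p$n)
  structure(list(slope_b = trend_slope(x, y), r = r, p_value = tt$p_value,
                 n_used = p$n, significance = tt$significance),
            class = "trend_result")
}

#' Validation metrics for extracted stage dates
#'
#' RMSE, MAE and MAPE of extracted against observed stage DOYs:
#' \deqn{RMSE = \sqrt{\frac{1}{n}\sum (Y_i - Y_i')^2},\quad
#'       MAE = \frac{1}{n}\sum |Y_i - Y_i'|,\quad
#'       MAPE = \frac{100}{n}\sum \left|\frac{Y_i - Y_i'}{Y_i'}\right|}
#' with the observed DOY in the MAPE denominator. Lower values mean higher
#' extraction accuracy.
#'
#' @param extracted Extracted DOYs.
#' @param observed Observed (field) DOYs, all non-zero; same length.
#' @param stage Optional stage name carried into the report.
#' @return A `validation_report` list: `stage`, `rmse`, `mae`, `mape`
#'   (percent), `n`.
#' @examples
#' validation_metrics(c(170, 160), c(166, 168))
#' @export
validation_metrics <- function(extracted, observed, stage = NA_character_) {
  if (length(extracted) != length(observed))
    stop("`extracted` and `observed` must have the same length", call. = FALSE)
  if (length(extracted) < 1L) stop("need at least one pair", call. = FALSE)
  if (any(!is.finite(extracted)) || any(!is.finite(observed)))
    stop("validation inputs must be finite", call. = FALSE)
  if (any(observed == 0))
    stop("observed DOY of 0 makes MAPE undefined", call. = FALSE)
  err <- extracted - observed
  structure(list(stage = stage,
                 rmse = sqrt(mean(err^2)),
                 mae = mean(abs(err)),
                 mape = mean(abs(err / observed)) * 100,
                 n = length(err)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report>%s n=%d  RMSE %.2f d  MAE %.2f d  MAPE %.2f%%\n",
              if (is.na(x$stage)) "" else paste0(" ", x$stage), x$n,
              x$rmse, x$mae, x$mape))
  invisible(x)
}

#' Area fractions of a stage-date map by DOY bin
#'
#' Bins detected per-pixel stage DOYs into half-open classes `[lo, hi)` and
#' reports the fraction of the masked, detected area in each. `bin_edges` are
#' the interior edges; open outer bins below the first and above the last
#' edge are added automatically, so fractions always sum to 1.
#'
#' @param doys Numeric matrix/vector of per-pixel stage DOYs (`NA` =
#'   undetected).
#' @param bin_edges Increasing interior DOY edges (e.g. `c(161, 177)`).
#' @param mask Logical mask of analysis pixels (default: all).
#' @return A data.frame with `bin` label, `lo`, `hi`, `count`, `fraction`.
#' @examples
#' doy_bin_summary(c(150, 165, 170, 200), c(161, 177))
#' @export
doy_bin_summary <- function(doys, bin_edges, mask = NULL) {
  v <- as.numeric(doys)
  if (is.null(mask)) mask <- rep(TRUE, length(v))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (any(diff(bin_edges) <= 0))
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  v <- v[as.logical(mask)]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no detected pixels under the mask", call. = FALSE)
  edges <- c(-Inf, as.numeric(bin_edges), Inf)
  counts <- as.integer(table(cut(v, breaks = edges, right = FALSE)))
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  data.frame(bin = sprintf("[%s, %s)", lo, hi), lo = lo, hi = hi,
             count = counts, fraction = counts / length(v),
             stringsAsFactors = FALSE)
}
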