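#' Double-logistic seasonal NDVI model
#'
#' Canonical unimodal crop trajectory used by the scene generator:
#' \deqn{NDVI(t) = v_{min} + (v_{max} - v_{min})\,[\sigma(m_1 (t - s_1)) +
#'   \sigma(-m_2 (t - s_2)) - 1]}
#' with \eqn{\sigma} the logistic function, \eqn{s_1}/\eqn{s_2} the rising and
#' falling inflection DOYs and \eqn{m_1}/\eqn{m_2} the corresponding rates
#' (1/day). The curve approaches `v_min` far from the season and is unimodal
#' when the inflections are well separated relative to `1/m1 + 1/m2`.
#'
#' @param t DOY (vectorized).
#' @param v_min,v_max Background and peak NDVI; `v_min < v_max`.
#' @param m1,s1 Rate and DOY of the green-up inflection.
#' @param m2,s2 Rate and DOY of the senescence inflection.
#' @param deriv If `TRUE`, return the analytic first derivative (NDVI/day).
#' @return NDVI values (or derivative) at `t`.
#' @examples
#' double_logistic(165)   # halfway up the green-up limb
#' @export
double_logistic <- function(t, v_min = 0.15, v_max = 0.85,
                            m1 = 0.10, s1 = 165, m2 = 0.08, s2 = 262,
                            deriv = FALSE) {
  if (v_min >= v_max) stop("`v_min` must be < `v_max`", call. = FALSE)
  if (m1 <= 0 || m2 <= 0) stop("rates `m1`, `m2` must be > 0", call. = FALSE)
  amp <- v_max - v_min
  p1 <- stats::plogis(m1 * (t - s1))
  p2 <- stats::plogis(-m2 * (t - s2))
  if (deriv) {
    amp * (m1 * p1 * (1 - p1) - m2 * p2 * (1 - p2))
  } else {
    v_min + amp * (p1 + p2 - 1)
  }
}

#' True stage dates of a noiseless double-logistic curve
#'
#' Numeric ground truth for the stage detectors: on a fine DOY grid
#' (0.01-day resolution after refinement) of the noiseless curve, tasseling
#' is the argmax of the curve, jointing the argmax of its derivative before
#' the peak, and maturity the argmin of the derivative after the peak. For
#' well-separated inflections these sit at `s1` and `s2` (the logistic
#' inflection points).
#'
#' @inheritParams double_logistic
#' @param from,to DOY search range (defaults 97-297, the composite season).
#' @return Named numeric vector `c(jointing, tasseling, maturity)`.
#' @examples
#' true_stage_dates()   # about (165, 211, 262) with the defaults
#' @export
true_stage_dates <- function(v_min = 0.15, v_max = 0.85,
                             m1 = 0.10, s1 = 165, m2 = 0.08, s2 = 262,
                             from = 97, to = 297) {
  if (s1 >= s2) stop("`s1` must precede `s2`", call. = FALSE)
  f <- function(t, d = FALSE)
    double_logistic(t, v_min, v_max, m1, s1, m2, s2, deriv = d)
  refine <- function(t0, score, lo, hi) {
    # coarse-to-fine argmax of `score` at 0.01-day resolution
    g <- seq(max(lo, t0 - 0.2), min(hi, t0 + 0.2), by = 0.01)
    g[which.max(score(g))]
  }
  coarse <- seq(from, to, by = 0.1)
  tas0 <- coarse[which.max(f(coarse))]
  tasseling <- refine(tas0, f, from, to)
  pre <- coarse[coarse < tasseling]
  post <- coarse[coarse > tasseling]
  if (length(pre) == 0L || length(post) == 0L)
    stop("curve is not unimodal inside the search range", call. = FALSE)
  joi0 <- pre[which.max(f(pre, d = TRUE))]
  mat0 <- post[which.min(f(post, d = TRUE))]
  jointing <- refine(joi0, function(t) f(t, d = TRUE), from, tasseling)
  maturity <- refine(mat0, function(t) -f(t, d = TRUE), tasseling, to)
  if (!(jointing < tasseling && tasseling < maturity) ||
      f(jointing, d = TRUE) <= 0 || f(maturity, d = TRUE) >= 0)
    stop("curve is not unimodal inside the search range", call. = FALSE)
  c(jointing = jointing, tasseling = tasseling, maturity = maturity)
}

#' Configuration of a synthetic NDVI scene
#'
#' Parameters of the synthetic study: a grid of maize pixels observed over a
#' set of years as 26 NDVI composites (8-day step, DOY 97-297), each
#' pixel-year following a double-logistic trajectory whose inflection DOYs
#' are drawn around `s1_mean`/`s2_mean` with optional interannual drift,
#' plus additive Gaussian noise and random cloud dropouts, monthly
#' meteorological covariates with a prescribed coupling to the true stage
#' dates, and site observations drawn from the truth.
#'
#' @param n_rows,n_cols Scene size in pixels.
#' @param years Calendar years simulated.
#' @param v_min,v_max,m1,m2 Double-logistic shape shared by all pixels.
#' @param s1_mean,s2_mean Mean rising/falling inflection DOYs in the first
#'   year.
#' @param s1_sd,s2_sd Pixel-year jitter: standard deviation when
#'   `jitter_dist = "normal"`, half-range when `"uniform"`.
#' @param jitter_dist `"normal"` or `"uniform"` draw of the inflection DOYs.
#' @param trend_s1,trend_s2 Linear drift of the mean inflection DOYs in
#'   days/year across `years`.
#' @param noise_sd Additive Gaussian noise on each composite (NDVI units).
#' @param dropout_p Per-composite probability of a cloud dropout (weight 0,
#'   value additionally depressed as clouds do).
#' @param met_coupling_r Target Pearson correlation between true stage DOYs
#'   and the preceding-month temperature covariate.
#' @param met_coupling_r_precip Same for the precipitation covariate
#'   (default 0: independent).
#' @param n_sites_per_year Site observations emitted per year.
#' @param seed Integer RNG seed; the whole scene is reproducible from it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_rows = 20L, n_cols = 20L, years = 2003:2022,
                         v_min = 0.15, v_max = 0.85, m1 = 0.10, m2 = 0.08,
                         s1_mean = 165, s1_sd = 4, s2_mean = 262, s2_sd = 4,
                         jitter_dist = c("normal", "uniform"),
                         trend_s1 = 0, trend_s2 = 0,
                         noise_sd = 0.03, dropout_p = 0.1,
                         met_coupling_r = -0.6, met_coupling_r_precip = 0,
                         n_sites_per_year = 3L, seed = 42L) {
  jitter_dist <- match.arg(jitter_dist)
  if (v_min >= v_max) stop("`v_min` must be < `v_max`", call. = FALSE)
  if (s1_mean >= s2_mean) stop("`s1_mean` must precede `s2_mean`", call. = FALSE)
  if (dropout_p < 0 || dropout_p >= 1)
    stop("`dropout_p` must be in [0, 1)", call. = FALSE)
  if (abs(met_coupling_r) > 1 || abs(met_coupling_r_precip) > 1)
    stop("met couplings must be within [-1, 1]", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 years = as.integer(years), v_min = v_min, v_max = v_max,
                 m1 = m1, m2 = m2, s1_mean = s1_mean, s1_sd = s1_sd,
                 s2_mean = s2_mean, s2_sd = s2_sd, jitter_dist = jitter_dist,
                 trend_s1 = trend_s1, trend_s2 = trend_s2,
                 noise_sd = noise_sd, dropout_p = dropout_p,
                 met_coupling_r = met_coupling_r,
                 met_coupling_r_precip = met_coupling_r_precip,
                 n_sites_per_year = as.integer(n_sites_per_year),
                 seed = as.integer(seed)),
            class = "scene_config")
}

# monthly LST (deg C) and precipitation (mm) climatology for months 4..9,
# loosely matching a cold-temperate plain growing season
.met_clim <- list(
  months = 4:9,
  lst_mean = c(8, 14, 19, 22, 21, 14), lst_sd = 1.5,
  precip_mean = c(40, 60, 90, 110, 100, 70), precip_sd = 25,
  # stage truth coupled to the covariate of the month preceding the stage:
  # jointing (June) <- May, tasseling (July) <- June, maturity (Sep) <- August
  coupled = c(jointing = 5L, tasseling = 6L, maturity = 8L))

#' Generate a synthetic NDVI scene with known ground truth
#'
#' Deterministically (given `cfg$seed`) simulates the full study inputs: an
#' NDVI composite cube with validity weights, a crop mask, the per-pixel-year
#' true stage dates derived from the noiseless curves on a fine grid, site
#' observations sampled from the truth, and monthly temperature/precipitation
#' cubes whose May/June/August values mix the standardized true stage DOYs
#' with independent noise so that their pixelwise correlation with the truth
#' equals the configured coupling in expectation.
#'
#' @param cfg A [scene_config()].
#' @return A list of class `synthetic_scene`: `ndvi` (an `ndvi_cube`),
#'   `truth` (data.frame: row, col, year, s1, s2, jointing, tasseling,
#'   maturity), `sites` (data.frame: site_id, lon, lat, row, col, year,
#'   stage, observed_doy), `met` (list of `met_cube`: `lst`, `precip`), and
#'   `config`.
#' @examples
#' sc <- generate_scene(scene_config(n_rows = 2, n_cols = 2, years = 2021:2022,
#'                                   n_sites_per_year = 1))
#' head(sc$truth)
#' @export
generate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  nr <- cfg$n_rows; nc <- cfg$n_cols; years <- cfg$years
  ny <- length(years); npx <- nr * nc
  doys <- seq(97L, 297L, by = 8L)
  nd <- length(doys)
  jitter <- function(n, sd) {
    if (sd == 0) return(rep(0, n))
    if (cfg$jitter_dist == "uniform") stats::runif(n, -sd, sd)
    else stats::rnorm(n, 0, sd)
  }
  s1 <- matrix(rep(cfg$s1_mean + cfg$trend_s1 * (years - years[1]),
                   each = npx), npx, ny) + matrix(jitter(npx * ny, cfg$s1_sd), npx, ny)
  s2 <- matrix(rep(cfg$s2_mean + cfg$trend_s2 * (years - years[1]),
                   each = npx), npx, ny) + matrix(jitter(npx * ny, cfg$s2_sd), npx, ny)

  values <- array(NA_real_, dim = c(nr, nc, ny * nd))
  weight <- array(1L, dim = c(nr, nc, ny * nd))
  truth <- data.frame(row = rep(rep(seq_len(nr), times = nc), ny),
                      col = rep(rep(seq_len(nc), each = nr), ny),
                      year = rep(years, each = npx),
                      s1 = as.vector(s1), s2 = as.vector(s2),
                      jointing = NA_real_, tasseling = NA_real_,
                      maturity = NA_real_)
  for (yi in seq_len(ny)) {
    bands <- (yi - 1L) * nd + seq_len(nd)
    for (p in seq_len(npx)) {
      r <- (p - 1L) %% nr + 1L; c_ <- (p - 1L) %/% nr + 1L
      v <- double_logistic(doys, cfg$v_min, cfg$v_max,
                           cfg$m1, s1[p, yi], cfg$m2, s2[p, yi])
      if (cfg$noise_sd > 0) v <- v + stats::rnorm(nd, 0, cfg$noise_sd)
      w <- rep(1L, nd)
      if (cfg$dropout_p > 0) {
        drop <- stats::runif(nd) < cfg$dropout_p
        if (any(drop)) {
          w[drop] <- 0L
          # clouds depress apparent NDVI as well as flagging it
          v[drop] <- v[drop] - stats::runif(sum(drop), 0.1, 0.4)
        }
      }
      v <- pmin(pmax(v, -1), 1)
      values[r, c_, bands] <- v
      weight[r, c_, bands] <- w
      tr <- (yi - 1L) * npx + p
      truth[tr, c("jointing", "tasseling", "maturity")] <-
        true_stage_dates(cfg$v_min, cfg$v_max, cfg$m1, s1[p, yi],
                         cfg$m2, s2[p, yi])
    }
  }
  grid <- grid_geometry(xmin = 130, ymax = 48, xres = 0.0025, yres = 0.0025,
                        nrow = nr, ncol = nc)
  cube <- ndvi_cube(values, weight, years = years, doys = doys,
                    mask = matrix(TRUE, nr, nc), grid = grid)

  sites <- synth_sites(cfg, truth, grid)
  met <- synth_met(cfg, truth, grid)
  structure(list(ndvi = cube, truth = truth, sites = sites, met = met,
                 config = cfg),
            class = "synthetic_scene")
}

synth_sites <- function(cfg, truth, grid) {
  years <- cfg$years
  stages <- c("jointing", "tasseling", "maturity")
  out <- vector("list", length(years))
  sid <- 0L
  for (yi in seq_along(years)) {
    rows <- truth[truth$year == years[yi], , drop = FALSE]
    k <- min(cfg$n_sites_per_year, nrow(rows))
    pick <- sample(nrow(rows), k)
    st <- sample(stages, k, replace = TRUE)
    obs <- round(rows[cbind(pick, match(st, names(rows)))])
    out[[yi]] <- data.frame(
      site_id = sprintf("S%04d", sid + seq_len(k)),
      lon = grid$xmin + (rows$col[pick] - 0.5) * grid$xres,
      lat = grid$ymax - (rows$row[pick] - 0.5) * grid$yres,
      row = rows$row[pick], col = rows$col[pick],
      year = years[yi], stage = st, observed_doy = as.integer(obs),
      stringsAsFactors = FALSE)
    sid <- sid + k
  }
  do.call(rbind, out)
}

# covariate = mu + sd * (rho * z_truth + sqrt(1 - rho^2) * eps) so that
# cor(covariate, truth DOY) = rho in expectation per pixel
synth_met <- function(cfg, truth, grid) {
  nr <- cfg$n_rows; nc <- cfg$n_cols; years <- cfg$years
  ny <- length(years); npx <- nr * nc
  clim <- .met_clim
  zscore <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  make_cube <- function(mu, sdev, rho, variable) {
    vals <- array(NA_real_, dim = c(nr, nc, ny, 12L))
    for (mi in seq_along(clim$months)) {
      m <- clim$months[mi]
      stage <- names(clim$coupled)[match(m, clim$coupled)]
      eps <- matrix(stats::rnorm(npx * ny), npx, ny)
      if (!is.na(stage) && rho != 0) {
        z <- matrix(NA_real_, npx, ny)
        for (p in seq_len(npx)) {
          idx <- seq(p, by = npx, length.out = ny)
          z[p, ] <- zscore(truth[[stage]][idx])
        }
        mix <- rho * z + sqrt(1 - rho^2) * eps
      } else mix <- eps
      for (yi in seq_len(ny))
        vals[, , yi, m] <- matrix(mu[mi] + sdev * mix[, yi], nr, nc)
    }
    if (variable == "precip_sum_monthly") vals <- pmax(vals, 0)
    met_cube(vals, years = years, grid = grid, variable = variable)
  }
  list(lst = make_cube(clim$lst_mean, clim$lst_sd, cfg$met_coupling_r,
                       "lst_mean_monthly"),
       precip = make_cube(clim$precip_mean, clim$precip_sd,
                          cfg$met_coupling_r_precip, "precip_sum_monthly"))
}

#' Per-pixel truth array for one stage
#'
#' Reshapes a scene's truth table into a `[row, col, year]` array, the layout
#' the map-level analytics consume.
#'
#' @param scene A [generate_scene()] result.
#' @param stage `"jointing"`, `"tasseling"` or `"maturity"`.
#' @return Numeric array `[n_rows, n_cols, n_years]`.
#' @export
truth_array <- function(scene, stage = c("jointing", "tasseling", "maturity")) {
  stage <- match.arg(stage)
  cfg <- scene$config
  array(scene$truth[[stage]],
        dim = c(cfg$n_rows, cfg$n_cols, length(cfg$years)))
}
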