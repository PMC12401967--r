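test_that("monthly aggregation pools LST means and sums precipitation", {
  # 30 daily LST samples of 300 K in one month -> 26.85 deg C
  vals <- array(300, dim = c(2, 2, 30))
  lst <- aggregate_monthly(vals, as.Date("2010-06-01") + 0:29,
                           "lst_mean_monthly", units = "K")
  expect_equal(lst$values[1, 1, 1, 6], 300 - 273.15)
  expect_true(all(is.na(lst$values[, , 1, 7])))
  # 24 hourly millimetre depths on one day, zero elsewhere -> 24 mm
  pv <- array(0, dim = c(1, 1, 24 * 10))
  pv[1, 1, 25:48] <- 1
  times <- rep(as.Date("2010-07-01") + 0:9, each = 24)
  pr <- aggregate_monthly(pv, times, "precip_sum_monthly")
  expect_equal(pr$values[1, 1, 1, 7], 24)
  # mixed day/night LST pools all samples equally
  set.seed(15)
  mix <- array(rnorm(4 * 4 * 14, 20, 5), dim = c(4, 4, 14))
  m <- aggregate_monthly(mix, rep(as.Date("2011-05-03") + 0:6, 2),
                         "lst_mean_monthly")
  expect_equal(m$values[, , 1, 5], apply(mix, c(1, 2), mean))
  # a month inside the span with no samples warns and stays missing
  expect_warning(
    aggregate_monthly(array(1, dim = c(1, 1, 2)),
                      as.Date(c("2012-05-10", "2012-07-10")),
                      "lst_mean_monthly"),
    "2012-06")
})

test_that("nearest-neighbour regridding copies containing-cell values", {
  src_grid <- grid_geometry(0, 4, 1, 1, nrow = 4, ncol = 4)
  vals <- array(NA_real_, dim = c(4, 4, 1, 12))
  vals[, , 1, 5] <- matrix(1:16, 4, 4)
  cube <- met_cube(vals, years = 2020, grid = src_grid, "lst_mean_monthly")
  # identical grids: identity
  same <- regrid_to_analysis(cube, src_grid)
  expect_equal(same$values, cube$values)
  # 2x2 block refinement copies each source value into its block
  coarse <- met_cube(vals[1:2, 1:2, , , drop = FALSE] , years = 2020,
                     grid = grid_geometry(0, 4, 2, 2, 2, 2), "lst_mean_monthly")
  fine <- regrid_to_analysis(coarse, grid_geometry(0, 4, 1, 1, 4, 4))
  for (r in 1:4) for (c in 1:4)
    expect_equal(fine$values[r, c, 1, 5],
                 coarse$values[ceiling(r / 2), ceiling(c / 2), 1, 5])
  # offset target grid: brute-force point-in-cell oracle
  tgt <- grid_geometry(0.3, 3.6, 0.7, 0.9, nrow = 3, ncol = 5)
  rg <- regrid_to_analysis(cube, tgt)
  for (r in 1:3) for (c in 1:5) {
    x <- 0.3 + (c - 0.5) * 0.7
    y <- 3.6 - (r - 0.5) * 0.9
    sr <- floor(4 - y) + 1
    sc <- floor(x) + 1
    expect_equal(rg$values[r, c, 1, 5], vals[sr, sc, 1, 5])
  }
  # disjoint extents cannot be regridded
  expect_error(regrid_to_analysis(cube, grid_geometry(100, 200, 1, 1, 2, 2)),
               "disjoint")
})

test_that("stage-covariate correlation reduces to the Pearson primitive", {
  set.seed(33)
  nr <- 6; nc <- 5; ny <- 15
  years <- 2001:2015
  doys <- array(rnorm(nr * nc * ny, 168, 5), dim = c(nr, nc, ny))
  met_vals <- array(NA_real_, dim = c(nr, nc, ny, 12))
  met_vals[, , , 5] <- doys * 0.3 + rnorm(nr * nc * ny, 0, 0.01)
  met <- met_cube(pmax(met_vals, 0), years = years,
                  variable = "precip_sum_monthly")
  pc <- correlate_stage_met(doys, years, met, stage_month = 6, lag_months = 1)
  expect_equal(pc$covariate_month, 5)
  # near-perfect construction: r ~ 1 and extremely significant
  expect_true(all(pc$r > 0.99))
  expect_true(all(pc$significance == "p01"))
  # per-pixel equality with the scalar primitive at random pixels
  for (i in 1:10) {
    r <- sample(nr, 1); c <- sample(nc, 1)
    expect_equal(pc$r[r, c], pearson_r(met$values[r, c, , 5], doys[r, c, ]))
  }
  # too few overlapping years -> undetected pixel
  doys2 <- doys; doys2[1, 1, 3:15] <- NA
  pc2 <- correlate_stage_met(doys2, years, met, 6)
  expect_true(is.na(pc2$r[1, 1]))
})

test_that("dominant factor takes the larger |r| with ties to precipitation", {
  rt <- matrix(c(0.5, -0.3, 0.4, NA, NA, 0.2), 2, 3)
  rp <- matrix(c(-0.7, 0.1, -0.4, 0.9, NA, NA), 2, 3)
  dm <- dominant_factor(rt, rp)
  expect_equal(dm$label[1, 1], "precipitation")   # |-0.7| > |0.5|
  expect_equal(dm$label[2, 1], "temperature")     # |-0.3| > |0.1|
  expect_equal(dm$label[1, 2], "precipitation")   # exact tie rule
  expect_equal(dm$label[2, 2], "precipitation")   # only precip available
  expect_true(is.na(dm$label[1, 3]))              # both missing
  expect_equal(dm$label[2, 3], "temperature")
  expect_equal(sum(dm$fractions$fraction), 1)
  expect_equal(dm$r_win[1, 1], 0.7)
})
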