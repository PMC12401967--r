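test_that("Pearson correlation matches direct evaluation and its symmetries", {
  x <- 1:5
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3, 5)), 0.8)
  expect_equal(pearson_r(c(2, 1, 4, 3, 5), x), 0.8)           # symmetric
  expect_equal(pearson_r(10 + 3 * x, c(2, 1, 4, 3, 5)), 0.8)  # affine invariant
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "3 complete")
  # missing years drop out pairwise
  expect_equal(pearson_r(c(x, 6), c(2, 1, 4, 3, 5, NA)), 0.8)
})

test_that("trend slope is the OLS estimator with sign semantics in days/year", {
  x <- 1:6
  expect_equal(trend_slope(x, 2 * x), 2)
  expect_equal(trend_slope(x, rep(3.3, 6)), 0)
  years <- 2003:2022
  expect_equal(trend_slope(years, 168 - 0.43 * (years - 2003)), -0.43,
               tolerance = 1e-12)
  # b = r * s_y / s_x on random pairs
  set.seed(30)
  for (i in 1:20) {
    xr <- rnorm(15); yr <- 0.4 * xr + rnorm(15)
    expect_equal(trend_slope(xr, yr),
                 pearson_r(xr, yr) * sd(yr) / sd(xr), tolerance = 1e-10)
    # location shifts change neither b nor r
    expect_equal(trend_slope(xr + 100, yr - 7), trend_slope(xr, yr),
                 tolerance = 1e-10)
    expect_equal(pearson_r(xr + 100, yr - 7), pearson_r(xr, yr),
                 tolerance = 1e-10)
  }
})

test_that("correlation t-test classifies significance at 0.05 and 0.01", {
  expect_equal(t_test_r(0, 10)$p_value, 1)
  expect_equal(t_test_r(0, 10)$significance, "ns")
  # r = 0.9, n = 5: t = 3.576 on 3 df
  res <- t_test_r(0.9, 5)
  expect_equal(res$p_value,
               2 * pt(-0.9 * sqrt(3 / (1 - 0.81)), df = 3), tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$significance, "p05")
  # critical r for df = 18 at alpha = 0.05 sits right on the boundary
  tcrit <- qt(0.975, 18)
  rcrit <- sqrt(tcrit^2 / (tcrit^2 + 18))
  expect_equal(t_test_r(rcrit, 20)$p_value, 0.05, tolerance = 1e-10)
  expect_equal(t_test_r(rcrit * 1.001, 20)$significance, "p05")
  expect_equal(t_test_r(rcrit * 0.999, 20)$significance, "ns")
  expect_equal(t_test_r(1, 10)$p_value, 0)
  expect_equal(t_test_r(-0.99999, 20)$significance, "p01")
})

test_that("validation metrics reproduce hand-computed RMSE/MAE/MAPE", {
  z <- validation_metrics(c(150, 170), c(150, 170))
  expect_equal(c(z$rmse, z$mae, z$mape), c(0, 0, 0))
  v <- validation_metrics(c(170, 160), c(166, 168))
  expect_equal(v$mae, 6)
  expect_equal(v$rmse, sqrt((16 + 64) / 2))
  expect_equal(v$mape, (4 / 166 + 8 / 168) / 2 * 100, tolerance = 1e-12)
  expect_equal(round(v$mape, 3), 3.586)
  single <- validation_metrics(100, 104)
  expect_equal(single$rmse, 4)
  expect_equal(single$mae, 4)
  expect_equal(single$mape, 400 / 104, tolerance = 1e-12)
  expect_error(validation_metrics(1:3, 1:2), "length")
  expect_error(validation_metrics(5, 0), "undefined")
})

test_that("RMSE dominates MAE with equality only for equal absolute errors", {
  set.seed(44)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    e <- rnorm(n, 0, 5)
    v <- validation_metrics(160 + e, rep(160, n))
    expect_gte(v$rmse, v$mae - 1e-12)
  }
  eq <- validation_metrics(c(163, 157, 163), c(160, 160, 160))
  expect_equal(eq$rmse, eq$mae)
})

test_that("DOY bins are half-open classes whose fractions sum to one", {
  b <- doy_bin_summary(rep(165, 10), c(161, 177))
  expect_equal(b$fraction[b$lo == 161], 1)
  b2 <- doy_bin_summary(c(150, 165, 170, 200), c(161, 177))
  expect_equal(b2$fraction, c(0.25, 0.5, 0.25))
  expect_equal(sum(b2$fraction), 1, tolerance = 1e-12)
  # boundary value falls in the upper class of a half-open edge
  b3 <- doy_bin_summary(c(160, 161), c(161, 177))
  expect_equal(b3$count[1:2], c(1L, 1L))
  # undetected pixels and the mask are excluded before binning
  m <- matrix(c(150, 165, NA, 200), 2, 2)
  b4 <- doy_bin_summary(m, c(161, 177), mask = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  expect_equal(sum(b4$count), 2L)
  expect_error(doy_bin_summary(m, c(161, 177), mask = matrix(FALSE, 2, 2)),
               "empty mask")
  # Gaussian stage map: the central class carries the normal mass
  set.seed(8)
  d <- rnorm(4000, 168, 5)
  g <- doy_bin_summary(d, c(161, 177))
  mass <- pnorm(177, 168, 5) - pnorm(161, 168, 5)
  se <- sqrt(mass * (1 - mass) / 4000)
  expect_lt(abs(g$fraction[2] - mass), 3 * se)
})
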