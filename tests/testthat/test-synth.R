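test_that("double-logistic evaluates to its closed form", {
  # halfway up the green-up limb when the senescence term is saturated
  expect_equal(double_logistic(165), 0.15 + 0.7 * (0.5 + plogis(0.08 * 97) - 1),
               tolerance = 1e-12)
  # mid-season with both terms saturated the curve sits at the plateau
  expect_lt(abs(double_logistic(213, m1 = 0.3, m2 = 0.3) - 0.85), 1e-4)
  # at the default gentler rates the plateau stays a little below v_max
  expect_lt(abs(double_logistic(213) - 0.85), 0.03)
  # direct arithmetic at an arbitrary DOY
  t <- 200
  expect_equal(double_logistic(t, 0.15, 0.85, 0.10, 165, 0.08, 262),
               0.15 + 0.7 * (plogis(0.10 * (t - 165)) +
                               plogis(-0.08 * (t - 262)) - 1))
  expect_error(double_logistic(100, v_min = 0.9, v_max = 0.2), "v_min")
  # analytic derivative agrees with a central difference
  h <- 1e-5
  expect_equal(double_logistic(180, deriv = TRUE),
               (double_logistic(180 + h) - double_logistic(180 - h)) / (2 * h),
               tolerance = 1e-7)
})

test_that("true stage dates sit at the logistic inflections and translate", {
  td <- true_stage_dates()
  oracle <- fine_grid_stages()
  expect_equal(unname(td), unname(oracle), tolerance = 0.02)
  # well-separated rates: inflections at s1 and s2
  expect_equal(unname(td["jointing"]), 165, tolerance = 0.05)
  expect_equal(unname(td["maturity"]), 262, tolerance = 0.05)
  # symmetric curve peaks at the midpoint
  sym <- true_stage_dates(m1 = 0.09, m2 = 0.09, s1 = 170, s2 = 240)
  expect_equal(unname(sym["tasseling"]), 205, tolerance = 0.02)
  # translation equivariance
  sh <- true_stage_dates(s1 = 175, s2 = 272)
  expect_equal(unname(sh - td), rep(10, 3), tolerance = 0.03)
  expect_error(true_stage_dates(s1 = 250, s2 = 240), "precede")
})

test_that("scenes are reproducible and noiseless scenes are exact", {
  cfg <- scene_config(n_rows = 3, n_cols = 3, years = 2021:2022,
                      noise_sd = 0, dropout_p = 0, s1_sd = 2, s2_sd = 2,
                      n_sites_per_year = 2, seed = 99)
  sc <- generate_scene(cfg)
  # composite values equal the analytic curve exactly
  i <- 7
  s <- cube_series(sc$ndvi, sc$truth$row[i], sc$truth$col[i], sc$truth$year[i])
  expect_equal(s$value,
               double_logistic(s$doy, s1 = sc$truth$s1[i], s2 = sc$truth$s2[i]),
               tolerance = 1e-12)
  # identical seeds give identical scenes, a different seed does not
  sc2 <- generate_scene(cfg)
  expect_identical(sc$ndvi$values, sc2$ndvi$values)
  expect_identical(sc$truth, sc2$truth)
  expect_identical(sc$met$lst$values, sc2$met$lst$values)
  sc3 <- generate_scene(scene_config(n_rows = 3, n_cols = 3,
                                     years = 2021:2022, noise_sd = 0,
                                     dropout_p = 0, s1_sd = 2, s2_sd = 2,
                                     n_sites_per_year = 2, seed = 100))
  expect_false(identical(sc$ndvi$values, sc3$ndvi$values))
  # site observations are drawn from the truth table
  st <- sc$sites
  for (j in seq_len(nrow(st))) {
    tr <- sc$truth[sc$truth$row == st$row[j] & sc$truth$col == st$col[j] &
                     sc$truth$year == st$year[j], ]
    expect_equal(st$observed_doy[j], round(tr[[st$stage[j]]]))
  }
})

test_that("the pipeline recovers truth on noiseless scenes within two days", {
  cfg <- scene_config(n_rows = 3, n_cols = 3, years = 2022, noise_sd = 0,
                      dropout_p = 0, s1_sd = 3, s2_sd = 3, seed = 5)
  sc <- generate_scene(cfg)
  maps <- extract_stage_maps(sc$ndvi)
  for (s in c("jointing", "tasseling", "maturity")) {
    err <- as.vector(maps[[s]][, , 1]) -
      sc$truth[[s]][order(sc$truth$col, sc$truth$row)]
    expect_lte(max(abs(err)), 2)
  }
})

test_that("met covariates carry the configured coupling to the truth", {
  cfg <- scene_config(n_rows = 10, n_cols = 25, years = 2003:2022,
                      met_coupling_r = -0.6, met_coupling_r_precip = 0,
                      seed = 77)
  sc <- generate_scene(cfg)
  doys <- truth_array(sc, "jointing")
  pc <- correlate_stage_met(doys, cfg$years, sc$met$lst, stage_month = 6)
  expect_lt(abs(mean(pc$r) - (-0.6)), 0.05)
  # the uncoupled covariate shows no systematic correlation
  pp <- correlate_stage_met(doys, cfg$years, sc$met$precip, stage_month = 6)
  expect_lt(abs(mean(pp$r)), 0.05)
})
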