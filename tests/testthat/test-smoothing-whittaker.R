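test_that("objective decomposes into fidelity and third-difference roughness", {
  y <- c(0.1, 0.2, 0.4, 0.3, 0.2)
  # z == y: pure roughness
  ob <- whittaker_objective(y, y, lambda = 1, diff_order = 3)
  expect_equal(ob$S, 0)
  expect_equal(ob$Q, ob$R)
  # hand expansion of the third differences of y
  r_hand <- sum(vapply(4:5, function(i)
    (y[i] - 3 * y[i - 1] + 3 * y[i - 2] - y[i - 3])^2, numeric(1)))
  expect_equal(ob$R, r_hand)
  # a degree-2 polynomial is annihilated by the d = 3 penalty
  z <- 0.1 + 0.02 * (1:10) + 0.003 * (1:10)^2
  expect_equal(whittaker_objective(rep(0, 10), z, 1, 3)$R, 0, tolerance = 1e-15)
  expect_error(whittaker_objective(y, y[1:3], 1), "length")
})

test_that("Whittaker solution matches a dense-matrix solve and its limits", {
  s <- dl_series(noise_sd = 0.03, seed = 11)
  # lambda = 0 with full weights returns the data exactly
  expect_equal(whittaker_smooth(s, lambda = 0)$value, s$value)
  # matches the dense linear-algebra oracle
  z <- whittaker_smooth(s, lambda = 10)$value
  expect_equal(z, whittaker_dense_oracle(s$value, rep(1, 26), 10, 3),
               tolerance = 1e-10)
  # with flagged samples the zero-weight rows drop out of the fidelity term
  w <- rep(1L, 26); w[c(6, 19)] <- 0L
  sw <- ndvi_series(s$doy, s$value, w)
  expect_equal(whittaker_smooth(sw, lambda = 10)$value,
               whittaker_dense_oracle(s$value, as.numeric(w), 10, 3),
               tolerance = 1e-10)
  # lambda -> Inf with d = 3 collapses onto the global quadratic fit
  z_inf <- whittaker_smooth(s, lambda = 1e8)$value
  fit <- lm(s$value ~ poly(seq_len(26), 2, raw = TRUE))
  expect_equal(z_inf, unname(fitted(fit)), tolerance = 1e-3)
  expect_error(whittaker_smooth(ndvi_series(s$doy, s$value, rep(0L, 26))),
               "degenerate")
})

test_that("roughness decreases and fidelity grows along a lambda ladder", {
  s <- dl_series(noise_sd = 0.04, seed = 3)
  lambdas <- 10^seq(-2, 5, by = 1)
  SR <- t(vapply(lambdas, function(l) {
    z <- whittaker_smooth(s, lambda = l)$value
    ob <- whittaker_objective(s, z, l)
    c(S = ob$S, R = ob$R)
  }, numeric(2)))
  expect_true(all(diff(SR[, "S"]) >= -1e-12))
  expect_true(all(diff(SR[, "R"]) <= 1e-12))
})

test_that("the solution minimizes Q against coordinate perturbations", {
  s <- dl_series(noise_sd = 0.03, seed = 5)
  lam <- 25
  z <- whittaker_smooth(s, lambda = lam)$value
  q0 <- whittaker_objective(s, z, lam)$Q
  for (i in seq_along(z)) {
    for (eps in c(-1e-4, 1e-4)) {
      zp <- z; zp[i] <- zp[i] + eps
      expect_gte(whittaker_objective(s, zp, lam)$Q, q0)
    }
  }
})

test_that("Whittaker smoothing is linear in the data", {
  doys <- doys8()
  set.seed(2)
  y1 <- runif(26, 0, 0.4); y2 <- runif(26, 0, 0.4)
  sm <- function(v) whittaker_smooth(ndvi_series(doys, v), lambda = 7)$value
  expect_equal(sm(0.5 * y1 + 0.3 * y2), 0.5 * sm(y1) + 0.3 * sm(y2),
               tolerance = 1e-10)
})

test_that("LOO-CV lambda selection agrees with the explicit refit oracle", {
  grid <- 10^seq(-1, 4, length.out = 13)
  # truth in the penalty null space: smoothing is pure variance reduction,
  # LOO error decreases with lambda and the heaviest smoothing wins
  # (a perfectly noiseless quadratic would make every lambda an exact tie)
  set.seed(19)
  quad <- ndvi_series(doys8(), 0.2 + ((seq_len(26) - 13)^2) / 400 +
                        rnorm(26, 0, 0.005))
  expect_equal(select_lambda(quad, grid), max(grid))
  cvq <- vapply(grid, function(l) loo_refit_oracle(quad, l), numeric(1))
  expect_equal(grid[which.min(cvq)], max(grid))
  # a one-element grid has nothing to choose
  s <- dl_series(noise_sd = 0.03, seed = 7)
  expect_equal(select_lambda(s, 3.5), 3.5)
  # argmin of the brute-force n-refit LOO curve
  cv <- vapply(grid, function(l) loo_refit_oracle(s, l), numeric(1))
  expect_equal(select_lambda(s, grid), grid[which.min(cv)])
  # ... also with cloud-flagged samples in play
  w <- rep(1L, 26); w[c(4, 17)] <- 0L
  sw <- ndvi_series(s$doy, s$value, w)
  cvw <- vapply(grid, function(l) loo_refit_oracle(sw, l), numeric(1))
  expect_equal(select_lambda(sw, grid), grid[which.min(cvw)])
  expect_error(select_lambda(s, numeric(0)), "non-empty")
  expect_error(select_lambda(s, c(1, -2)), "> 0")
})
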