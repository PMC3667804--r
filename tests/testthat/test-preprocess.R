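test_that("dummy-scan removal follows the acquisition layout", {
  syn <- coarse_si_syn()  # 5 dummies + 120 volumes
  run <- simulate_run(syn, "preop", seed = 1)$run
  expect_equal(dim(run$data)[4], 125L)
  dropped <- drop_dummies(run)
  expect_equal(dim(dropped$data)[4], 120L)
  expect_equal(dropped$n_dummy, 0L)
  expect_equal(dropped$data[, , , 1], run$data[, , , 6])
  ## n_dummy 0 is the identity
  expect_identical(drop_dummies(dropped), dropped)
  ## no volumes left after dummies -> precondition error
  broken <- run
  broken$n_dummy <- 125L
  expect_error(drop_dummies(broken), "n_dummy")
})

test_that("linear detrending removes ramps exactly and is idempotent", {
  u <- 0:119
  expect_lt(max(abs(detrend_linear(2 * u + 5))), 1e-10)
  ## sinusoid: matches the explicit least-squares projection oracle
  x <- sin(2 * pi * 0.05 * u * 2)
  X <- cbind(1, u)
  oracle <- x - drop(X %*% solve(crossprod(X), crossprod(X, x)))
  expect_equal(detrend_linear(x), oracle, tolerance = 1e-12)
  expect_equal(detrend_linear(oracle), oracle, tolerance = 1e-12)
  expect_lt(abs(mean(detrend_linear(x))), 1e-12)
})

test_that("ideal low-pass removes, preserves and projects as an ideal filter", {
  u <- 0:119
  ## 0.2 Hz is above the 0.08 Hz cutoff: power annihilated
  hi <- sin(2 * pi * 0.2 * u * 2)
  expect_lt(sum(lowpass(hi, 0.08, 2)^2) / sum(hi^2), 1e-10)
  ## a bin-aligned in-band sinusoid (k = 10, ~0.042 Hz) passes untouched
  lo <- sin(2 * pi * (10 / 240) * u * 2)
  expect_equal(lowpass(lo, 0.08, 2), lo, tolerance = 1e-8)
  ## white noise: filtered energy equals the Parseval sum over retained bins
  set.seed(8)
  x <- rnorm(120)
  y <- lowpass(x, 0.08, 2)
  f <- pmin(0:119, 120 - 0:119) / 240
  keep <- f <= 0.08 + 1e-12
  expect_equal(sum(y^2), sum(Mod(fft(x))[keep]^2) / 120, tolerance = 1e-8)
  ## variance shrinks by roughly the retained-bin fraction (39/120)
  expect_lt(abs(var(y) / var(x) - sum(keep) / 120), 0.15)
  ## idempotence and linearity
  expect_equal(lowpass(y, 0.08, 2), y, tolerance = 1e-10)
  z <- rnorm(120)
  expect_equal(lowpass(x + 2 * z, 0.08, 2),
               lowpass(x, 0.08, 2) + 2 * lowpass(z, 0.08, 2),
               tolerance = 1e-10)
  expect_error(lowpass(x, 0.25, 2), "Nyquist")
  ## the 4D fast path agrees with the per-voxel FFT path
  syn <- coarse_si_syn()
  run <- drop_dummies(simulate_run(syn, "preop", seed = 2)$run)
  lp4 <- lowpass(run, 0.08)
  v <- run$data[7, 9, 3, ]
  expect_equal(lp4$data[7, 9, 3, ], lowpass(v, 0.08, 2), tolerance = 1e-8)
})

test_that("detrend and low-pass commute on trend-free band-limited series", {
  ## construct a series exactly in the intersection of the two invariant
  ## subspaces: band-limited (bins 0..19) and orthogonal to the trend
  n <- 120; u <- 0:(n - 1)
  cols <- list(rep(1, n))
  for (k in 1:19) {
    w <- 2 * pi * k * u / n
    cols <- c(cols, list(cos(w)), list(sin(w)))
  }
  B <- do.call(cbind, cols)
  X <- cbind(1, u)
  M <- crossprod(X, B)            # 2 x 39
  ns <- svd(M, nu = 0, nv = ncol(B))$v[, 3:ncol(B)]
  set.seed(9)
  x <- drop(B %*% (ns %*% rnorm(ncol(ns))))
  a <- lowpass(detrend_linear(x), 0.08, 2)
  b <- detrend_linear(lowpass(x, 0.08, 2))
  expect_lt(max(abs(a - b)), 1e-8)
  expect_lt(max(abs(a - x)) / max(abs(x)), 1e-8)
})

test_that("Gaussian smoothing matches a dense convolution oracle", {
  set.seed(30)
  vol <- array(rnorm(9 * 9 * 5), c(9, 9, 5))
  run <- as_smooth_run(vol, c(1, 1, 1))
  sm <- smooth_run(run, fwhm_mm = 2)
  sigma <- 2 / (2 * sqrt(2 * log(2)))
  oracle <- dense_smooth_oracle(vol, rep(sigma, 3))
  expect_equal(sm$data[, , , 1], oracle, tolerance = 1e-10)
})

test_that("smoothing preserves constants, mass and the fwhm = 0 identity", {
  const <- array(3.7, c(8, 8, 4))
  run <- as_smooth_run(const, c(0.52, 0.52, 1))
  expect_equal(smooth_run(run, 7.8)$data[, , , 1], const, tolerance = 1e-12)
  expect_identical(smooth_run(run, 0), run)
  ## single-voxel impulse, FWHM 7.8 mm on 0.52 mm voxels: total mass kept
  imp <- array(0, c(56, 56, 56))
  imp[28, 28, 28] <- 5
  sm <- smooth_run(as_smooth_run(imp, c(0.52, 0.52, 0.52)), 7.8)
  expect_equal(sum(sm$data[, , , 1]), 5, tolerance = 5e-6)
})

test_that("quadratic-drift exclusion separates planted outliers from clean runs", {
  oc <- coarse_si_syn()
  set.seed(40)
  clean <- lapply(1:4, function(i)
    simulate_run(oc, "preop", rat_id = paste0("c", i), seed = 100 + i)$run)
  planted <- simulate_run(oc, "d1", rat_id = "outlier", seed = 200,
                          quad_amplitude = oc$nonlinear_drift_amplitude)$run
  res <- exclude_drift_runs(c(clean, list(planted)))
  expect_equal(res$table$rat_id[res$table$excluded], "outlier")
  expect_equal(length(res$kept), 4L)
  expect_equal(length(res$excluded), 1L)
  ## no outlier -> nothing excluded; infinite threshold -> nothing excluded
  res2 <- exclude_drift_runs(clean)
  expect_false(any(res2$table$excluded))
  res3 <- exclude_drift_runs(c(clean, list(planted)), quad_threshold = Inf)
  expect_false(any(res3$table$excluded))
})
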