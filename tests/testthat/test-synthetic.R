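test_that("atlas places mirrored SI and Hp boxes containing their seed points", {
  vs <- c(0.52, 0.52, 1)
  grid <- c(96L, 96L, 20L)
  a <- make_atlas(grid, vs)
  labs <- attr(a, "labels")
  org <- grid_origin(grid, vs)
  si <- mm_to_voxel(c(-4.2, -2.2, -0.2), vs, org)
  hp <- mm_to_voxel(c(-4.8, -2.4, -0.4), vs, org)
  expect_equal(a[si[1] + 1, si[2] + 1, si[3] + 1], labs[["SI_L"]])
  expect_equal(a[hp[1] + 1, hp[2] + 1, hp[3] + 1], labs[["Hp_L"]])
  m <- region_masks(a)
  expect_equal(sum(m$SI_L), sum(m$SI_R))
  expect_equal(sum(m$Hp_L), sum(m$Hp_R))
  ## right regions are exact mirror images in x
  expect_identical(m$SI_R[grid[1]:1, , ], m$SI_L[, , ])
  expect_identical(m$Hp_R[grid[1]:1, , ], m$Hp_L[, , ])
  ## all four disjoint
  expect_equal(sum(m$SI_L & m$SI_R), 0)
  expect_equal(sum(m$SI_L & m$Hp_L), 0)
})

test_that("impossible atlas geometry raises errors naming the region", {
  expect_error(make_atlas(c(4L, 4L, 2L), c(0.52, 0.52, 1)),
               "outside|overlaps")
  ## at half resolution the SI and Hp seed points share a voxel, so
  ## disjoint boxes containing both cannot exist
  expect_error(make_atlas(c(48L, 48L, 10L), c(50 / 48, 50 / 48, 2)),
               "overlaps")
})

test_that("simulated LFF is band-limited, standardized and reproducible", {
  set.seed(1)
  x <- simulate_lff(120, 2, c(0.01, 0.08))
  expect_lt(abs(mean(x)), 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  amp <- Mod(fft(x))
  f <- pmin(0:119, 120 - 0:119) / 240
  expect_lt(max(amp[f > 0.08 + 1e-9]), 1e-10)
  expect_lt(max(amp[f < 0.01 - 1e-9]), 1e-10)
  set.seed(5); a <- simulate_lff(120, 2)
  set.seed(5); b <- simulate_lff(120, 2)
  expect_identical(a, b)
  expect_error(simulate_lff(120, 2, c(0.01, 0.3)), "Nyquist")
})

test_that("LFF ensemble variance is unit", {
  set.seed(2)
  xs <- simulate_lff(120, 2, c(0.01, 0.08), n_series = 2000)
  expect_equal(mean(apply(xs, 2, var)), 1, tolerance = 1e-10)
})

test_that("session condition controls interhemispheric coupling", {
  syn <- tiny_syn()
  sim <- simulate_run(syn, "d1", seed = 11)
  cp <- sim$truth$coupling
  expect_equal(cp$amplitude[cp$hemisphere == "R"], c(0, 0))
  expect_true(all(cp$amplitude[cp$hemisphere == "L"] > 0))
  expect_error(simulate_run(syn, "day42"), "condition")

  ## preop: filtered homotopic regional means strongly correlated
  simp <- simulate_run(syn, "preop", seed = 12)
  m <- region_masks(make_atlas(syn$grid_shape, syn$voxel_size_mm,
                               syn$region_extent_px))
  run <- drop_dummies(simp$run)
  lt <- lowpass(detrend_linear(mask_mean_tc(run, m$SI_L)), 0.08, 2)
  rt <- lowpass(detrend_linear(mask_mean_tc(run, m$SI_R)), 0.08, 2)
  expect_gt(cor(lt, rt), 0.7)
})

test_that("uncoupled noise-only runs carry no structured correlation", {
  syn <- tiny_syn(coupling = default_coupling(0),
                  drift_slope_range = c(0, 0), physio = list())
  sim <- simulate_run(syn, "preop", seed = 13)
  pre <- preprocess_run(sim$run, fwhm_mm = 0)
  set.seed(14)
  ref <- lowpass(detrend_linear(rnorm(120)), 0.08, 2)
  cm <- correlation_map(pre, ref)
  expect_lt(abs(mean(cm$r, na.rm = TRUE)), 0.02)
  ## essentially nothing crosses the P < 2.5e-5 threshold
  expect_lt(mean(cm$r >= cm$r_critical, na.rm = TRUE), 5e-4)
})

test_that("cohort generation is complete, collision-safe and reproducible", {
  oc <- coarse_si_syn(n_volumes = 40L, n_dummy = 2L)
  dir <- file.path(tempdir(), "lffconn-cohort-test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  co <- simulate_cohort(oc, 3, include_drift_outlier = TRUE, out_dir = dir)
  expect_equal(nrow(co$manifest), 12L)
  expect_equal(length(co$truths), 12L)
  expect_equal(length(unique(co$manifest$rat_id[co$manifest$is_outlier])), 1L)
  expect_true(all(file.exists(file.path(dir, co$manifest$path))))
  expect_error(simulate_cohort(oc, 3, out_dir = dir), "collision")
  r <- read_run(file.path(dir, co$manifest$path[1]), n_dummy = 2)
  expect_equal(r$tr_s, 2)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_true(all(file.exists(man$path)))

  ## full-size cohort: n_rats x 4 runs, exactly one outlier rat
  co2 <- simulate_cohort(oc, 18, include_drift_outlier = TRUE)
  expect_equal(nrow(co2$manifest), 72L)
  expect_equal(sum(co2$manifest$is_outlier), 4L)
  expect_equal(length(unique(co2$manifest$rat_id[co2$manifest$is_outlier])),
               1L)
  truth_flags <- vapply(co2$truths, function(t) t$is_outlier, TRUE)
  expect_identical(truth_flags, co2$manifest$is_outlier)

  co3 <- simulate_cohort(oc, 1)
  expect_equal(nrow(co3$manifest), 4L)
  expect_false(any(co3$manifest$is_outlier))

  c4 <- simulate_cohort(oc, 2)
  c5 <- simulate_cohort(oc, 2)
  expect_identical(c4$manifest, c5$manifest)
  expect_identical(c4$runs[[3]]$data, c5$runs[[3]]$data)
})

test_that("Y-maze counts follow the truncated rounded-normal model", {
  tab <- simulate_ymaze(18, seed = 1)
  expect_equal(nrow(tab), 72L)
  expect_true(all(tab$trials_to_criterion >= 1L))
  means <- tapply(tab$trials_to_criterion, tab$condition, mean)
  mu <- c(27, 77, 70, 30); sds <- c(5, 18, 14, 6)
  expect_true(all(abs(means - mu) <= 3 * sds / sqrt(18)))
  t0 <- simulate_ymaze(5, c(a = 10, b = 20.4), c(a = 0, b = 0), seed = 2)
  expect_true(all(t0$trials_to_criterion[t0$condition == "a"] == 10L))
  expect_true(all(t0$trials_to_criterion[t0$condition == "b"] == 20L))
  expect_identical(simulate_ymaze(6, seed = 3), simulate_ymaze(6, seed = 3))
})

test_that("above-Nyquist physiological components alias as predicted", {
  base <- list(coupling = default_coupling(0), noise_sd = 1e-8,
               drift_slope_range = c(0, 0), baseline = 0)
  ## 1.05 Hz sampled at 0.5 Hz: alias |1.05 - 2*0.5| = 0.05 Hz, in-band
  syn <- do.call(tiny_syn, c(base, list(physio = list(resp = c(1.05, 5)))))
  tc <- drop_dummies(simulate_run(syn, "preop", seed = 4)$run)$data[5, 5, 3, ]
  sp <- amplitude_spectrum(tc - mean(tc), 2)
  expect_equal(sp$frequency[which.max(sp$amplitude)], 0.05)
  ## exactly 1 Hz aliases to DC: the sampled series is constant
  syn2 <- do.call(tiny_syn, c(base, list(physio = list(resp = c(1, 5)))))
  tc2 <- drop_dummies(simulate_run(syn2, "preop", seed = 4)$run)$data[5, 5, 3, ]
  expect_lt(sd(tc2), 1e-6)
})
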