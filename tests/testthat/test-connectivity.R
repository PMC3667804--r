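## small handmade run: 4x4x2 grid, unit voxels, centred origin
toy_run <- function(t_len = 20, fill = 0) {
  arr <- array(fill, c(4, 4, 2, t_len))
  bold_run(arr, c(1, 1, 1), tr_s = 2, n_dummy = 0L)
}

test_that("seed reference averages ROI voxels and flags degenerate seeds", {
  s <- sin(seq_len(20))
  run <- toy_run()
  set.seed(50)
  run$data[] <- rnorm(length(run$data))
  roi <- roi_spec("c", c(0, 0, 0), extent_px = c(2, 2, 1),
                  hemisphere = "L", region = "SI")
  vox <- roi_to_voxels(roi, run)
  for (i in seq_len(nrow(vox)))
    run$data[vox[i, 1] + 1, vox[i, 2] + 1, vox[i, 3] + 1, ] <- s
  expect_equal(seed_reference(run, roi), s, tolerance = 1e-12)

  ## all-constant ROI: degenerate seed
  flat <- toy_run(fill = 1)
  expect_error(seed_reference(flat, roi), "degenerate")

  ## antiphase pair: reference cancels to zero, caught downstream
  run2 <- toy_run()
  set.seed(51)
  run2$data[] <- rnorm(length(run2$data))
  pair <- roi_spec("p", c(0, 0, 0), extent_px = c(2, 1, 1),
                   hemisphere = "L", region = "SI")
  pv <- roi_to_voxels(pair, run2)
  run2$data[pv[1, 1] + 1, pv[1, 2] + 1, pv[1, 3] + 1, ] <- s
  run2$data[pv[2, 1] + 1, pv[2, 2] + 1, pv[2, 3] + 1, ] <- -s
  ref0 <- seed_reference(run2, pair)
  expect_lt(max(abs(ref0)), 1e-12)
  expect_error(correlation_map(run2, ref0), "degenerate")
})

test_that("correlation maps agree with the hand Pearson formula", {
  run <- toy_run(t_len = 5)
  ref <- c(1, 2, 3, 4, 5)
  v1 <- c(2, 4, 6, 8, 10)
  v2 <- c(1, 2, 3, 4, 100)
  run$data[1, 1, 1, ] <- v1
  run$data[2, 1, 1, ] <- v2
  run$data[3, 1, 1, ] <- -ref
  cm <- correlation_map(run, ref, p_threshold = NULL)
  expect_equal(cm$r[1, 1, 1], 1, tolerance = 1e-12)
  hand <- sum((v2 - mean(v2)) * (ref - mean(ref))) /
    sqrt(sum((v2 - mean(v2))^2) * sum((ref - mean(ref))^2))
  expect_equal(cm$r[2, 1, 1], hand, tolerance = 1e-12)
  expect_equal(cm$r[3, 1, 1], -1, tolerance = 1e-12)
  ## constant voxels are undefined, not zero
  expect_true(is.na(cm$r[4, 4, 2]))
})

test_that("correlation is invariant to affine rescaling of either input", {
  run <- toy_run()
  set.seed(52)
  run$data[] <- rnorm(length(run$data))
  ref <- rnorm(20)
  m1 <- correlation_map(run, ref, p_threshold = NULL)
  run2 <- run
  run2$data <- 3.2 * run$data + 11
  m2 <- correlation_map(run2, 0.5 * ref - 4, p_threshold = NULL)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
})

test_that("effective df follows the bandwidth-ratio rule", {
  expect_equal(effective_df(120, 2, 0.08), 36.4)
  ## near-Nyquist cutoff approaches the unfiltered limit n - 2
  expect_equal(effective_df(120, 2, 0.2499), 120 * 2 * 0.2499 * 2 - 2)
  expect_gt(effective_df(120, 2, 0.2499), 117.9)
  expect_error(effective_df(10, 2, 0.01), "df")
  expect_error(effective_df(120, 2, 0.3), "Nyquist")
})

test_that("critical correlation inverts the t threshold correctly", {
  expect_equal(r_critical(0.5, 36.4), 0, tolerance = 1e-12)
  expect_gt(r_critical(1e-5, 36.4), r_critical(1e-3, 36.4))
  expect_gt(r_critical(0.01, 36.4, "two-sided"),
            r_critical(0.01, 36.4, "one-sided"))
  ## closed-form consistency: t(r) recovers the t quantile
  r <- r_critical(2.5e-5, 36.4)
  tstat <- r * sqrt(36.4 / (1 - r^2))
  expect_equal(tstat, qt(1 - 2.5e-5, 36.4), tolerance = 1e-10)
})

test_that("supra-threshold counting equals enumeration and is monotone", {
  dims <- c(4, 4, 2)
  set.seed(53)
  rvals <- array(runif(prod(dims), -1, 1), dims)
  rvals[2, 2, 1] <- NA  # undefined voxel
  mk <- function(rc) structure(
    list(r = rvals, r_critical = rc, effective_df = 36.4,
         p_threshold = NA, sided = "one-sided"),
    class = "correlation_map")
  mask <- array(TRUE, dims)
  ## brute-force enumeration oracle
  cnt <- 0L
  for (i in 1:4) for (j in 1:4) for (k in 1:2)
    if (!is.na(rvals[i, j, k]) && rvals[i, j, k] >= 0.35) cnt <- cnt + 1L
  expect_equal(count_significant(mk(0.35), mask), cnt)
  ## all-ones map counts the whole mask; empty mask counts zero
  ones <- mk(0.75); ones$r <- array(1, dims)
  expect_equal(count_significant(ones, mask), prod(dims))
  expect_equal(count_significant(mk(0.35), array(FALSE, dims)), 0L)
  ## non-increasing in the threshold
  expect_gte(count_significant(mk(0.2), mask),
             count_significant(mk(0.6), mask))
})

test_that("count normalization reproduces the tables convention", {
  out <- normalize_counts(c(SI_R = 2, Hp_R = 50),
                          c(SI_R = 100, Hp_R = 50))
  expect_equal(out$normalized[out$region == "SI_R"], 0.02)
  expect_equal(out$normalized[out$region == "Hp_R"], 1.00)
  zero <- normalize_counts(c(SI_R = 3), c(SI_R = 0))
  expect_true(is.na(zero$normalized))
})

test_that("group maps handle degenerate voxels and recover group effects", {
  dims <- c(3, 3, 2)
  zeros <- lapply(1:5, function(i) array(0, dims))
  g0 <- group_tmap(zeros)
  expect_true(all(g0$t == 0))
  expect_true(all(g0$p == 1))
  expect_false(any(g0$significant))
  ## identical non-zero maps: zero variance -> undefined, not infinite
  same <- lapply(1:5, function(i) array(0.5, dims))
  g1 <- group_tmap(same)
  expect_true(all(is.na(g1$t)))
  expect_false(any(g1$significant))
  expect_error(group_tmap(zeros[1:2]), "at least 3")
  expect_error(group_tmap(list(array(0, dims), array(0, dims),
                               array(0, c(2, 2, 2)))), "grids")

  ## small synthetic group: bilateral SI coupling found in > 50% of masks
  syn <- tiny_syn()
  atlas <- make_atlas(syn$grid_shape, syn$voxel_size_mm,
                      syn$region_extent_px)
  m <- region_masks(atlas)
  maps <- lapply(1:6, function(i) {
    pre <- preprocess_run(simulate_run(syn, "preop", seed = 60 + i)$run)
    correlation_map(pre, seed_reference(pre, default_seed_rois()$SI))
  })
  g <- group_tmap(maps)
  expect_gt(mean(g$significant[m$SI_L]), 0.5)
  expect_gt(mean(g$significant[m$SI_R]), 0.5)
})

test_that("seed reference tracks the generating latent signal", {
  syn <- tiny_syn()
  sim <- simulate_run(syn, "preop", seed = 21)
  pre <- preprocess_run(sim$run)
  ref <- seed_reference(pre, default_seed_rois()$SI)
  latent <- lowpass(detrend_linear(sim$truth$latents$SI[-(1:5)]), 0.08, 2)
  expect_gt(cor(ref, latent), 0.9)
})
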