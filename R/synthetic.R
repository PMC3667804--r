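#' Default interhemispheric coupling table
#'
#' One row per (region, hemisphere, condition) giving the amplitude of the
#' shared homotopic low-frequency signal as a multiple of the white-noise
#' SD. The longitudinal design: bilateral coupling preoperatively, the
#' right-hemisphere amplitude abolished on postoperative days 1 and 3, and
#' restored on day 9.
#'
#' @param amplitude coupling amplitude (fraction of noise SD) for coupled
#'   region/hemisphere/condition cells. Default 1.2.
#' @param day9_amplitude amplitude used on day 9; defaults to the
#'   preoperative value (full restoration).
#' @return data.frame with columns `region, hemisphere, condition,
#'   amplitude`.
#' @export
default_coupling <- function(amplitude = 1.2, day9_amplitude = amplitude) {
  tab <- expand.grid(region = c("SI", "Hp"), hemisphere = c("L", "R"),
                     condition = c("preop", "d1", "d3", "d9"),
                     stringsAsFactors = FALSE)
  tab$amplitude <- ifelse(tab$condition == "d9", day9_amplitude, amplitude)
  off <- tab$hemisphere == "R" & tab$condition %in% c("d1", "d3")
  tab$amplitude[off] <- 0
  tab
}

#' Full generative parameterization for synthetic BOLD cohorts
#'
#' Collects every knob of the generator: grid geometry, acquisition timing
#' (120 volumes at TR 2 s after 5 dummy scans on a 96x96 matrix with 20
#' slices), the LFF band, the coupling design, noise and drift levels, and
#' the physiological components whose frequencies (~1 Hz respiration, ~5 Hz
#' cardiac in rats) exceed the 0.25 Hz Nyquist limit and alias into the
#' sampled series.
#'
#' @param grid_shape length-3 integer voxel grid (default `c(96, 96, 20)`).
#' @param voxel_size_mm length-3 voxel size in mm (default
#'   `c(0.52, 0.52, 1)`, a 50 mm in-plane field of view and 1 mm slices).
#' @param n_volumes number of resting-state volumes after dummies.
#' @param n_dummy leading steady-state volumes, later discarded.
#' @param tr_s repetition time in seconds.
#' @param lff_band_hz `(low, high)` band of the shared low-frequency signal;
#'   both bounds must lie within `[0, 1/(2 tr_s)]`.
#' @param coupling coupling table as from [default_coupling()].
#' @param noise_sd SD of voxelwise white noise, signal units.
#' @param baseline mean signal level (so percentage signal change is
#'   well defined).
#' @param drift_slope_range interval from which each run's linear drift
#'   slope is drawn, signal units per volume.
#' @param nonlinear_drift_amplitude end-of-run magnitude of the quadratic
#'   baseline planted in the drift-outlier rat's runs, signal units.
#' @param physio list of `c(freq_hz, amplitude)` pairs added as sinusoids
#'   evaluated at the sampling times (aliasing arises naturally); each
#'   voxel receives an independent uniform phase.
#' @param region_extent_px length-3 extent in voxels of each atlas region
#'   box (see [make_atlas()]).
#' @param regions which regions the atlas carries (`"SI"`, `"Hp"`).
#' @param rng_seed integer seed; identical `(config, seed)` reproduce
#'   byte-identical cohorts.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(96L, 96L, 20L),
                             voxel_size_mm = c(0.52, 0.52, 1),
                             n_volumes = 120L, n_dummy = 5L, tr_s = 2,
                             lff_band_hz = c(0.01, 0.08),
                             coupling = default_coupling(),
                             noise_sd = 10, baseline = 1000,
                             drift_slope_range = c(-0.05, 0.05),
                             nonlinear_drift_amplitude = 50,
                             physio = list(respiration = c(1.05, 3),
                                           cardiac = c(5.1, 2)),
                             region_extent_px = c(8L, 8L, 3L),
                             regions = c("SI", "Hp"),
                             rng_seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            n_volumes > 0L, n_dummy >= 0L, tr_s > 0, noise_sd > 0,
            nonlinear_drift_amplitude >= 0,
            length(drift_slope_range) == 2L,
            drift_slope_range[1] <= drift_slope_range[2])
  nyq <- 1 / (2 * tr_s)
  if (!(lff_band_hz[1] >= 0 && lff_band_hz[1] < lff_band_hz[2] &&
        lff_band_hz[2] <= nyq + 1e-12))
    stop("synthetic_config: lff_band_hz must satisfy 0 <= low < high <= ",
         "Nyquist (", nyq, " Hz)")
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 n_volumes = as.integer(n_volumes),
                 n_dummy = as.integer(n_dummy), tr_s = tr_s,
                 lff_band_hz = as.numeric(lff_band_hz),
                 coupling = coupling, noise_sd = noise_sd,
                 baseline = baseline,
                 drift_slope_range = as.numeric(drift_slope_range),
                 nonlinear_drift_amplitude = nonlinear_drift_amplitude,
                 physio = physio,
                 region_extent_px = as.integer(region_extent_px),
                 regions = match.arg(regions, c("SI", "Hp"),
                                     several.ok = TRUE),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

## atlas seed points (mm, left hemisphere); right regions mirror in x
atlas_seed_points <- function() {
  list(SI = c(-4.2, -2.2, -0.2), Hp = c(-4.8, -2.4, -0.4))
}

#' Build a toy rodent atlas label volume
#'
#' Places axis-aligned boxes for left/right primary somatosensory cortex
#' (SI) and hippocampus (Hp) on a centred grid. Each left-hemisphere box
#' contains the voxel holding its standard seed point (SI at
#' (-4.2, -2.2, -0.2) mm, Hp at (-4.8, -2.4, -0.4) mm); right-hemisphere
#' boxes are exact mirror images in x. Because the two seed points are only
#' ~0.6 mm apart, the SI box extends medially from its seed voxel and the
#' Hp box laterally, which keeps all four regions disjoint at the default
#' resolution.
#'
#' @param grid_shape length-3 integer grid.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param region_extent_px length-3 box extent in voxels (y and z centred
#'   on the seed voxel; x anchored as above).
#' @param regions subset of `c("SI", "Hp")` to place.
#' @param origin_mm atlas origin; default centres the grid (see
#'   [grid_origin()]).
#' @return Integer 3D array of class `lff_atlas`; labels are 0 (background)
#'   plus the values in `attr(, "labels")` (`SI_L`, `SI_R`, `Hp_L`,
#'   `Hp_R`). Errors, naming the offending region, if a box leaves the grid
#'   or two boxes overlap.
#' @export
make_atlas <- function(grid_shape, voxel_size_mm,
                       region_extent_px = c(8L, 8L, 3L),
                       regions = c("SI", "Hp"), origin_mm = NULL) {
  grid_shape <- as.integer(grid_shape)
  ex <- as.integer(region_extent_px)
  stopifnot(length(grid_shape) == 3L, length(ex) == 3L, all(ex >= 1L))
  if (is.null(origin_mm)) origin_mm <- grid_origin(grid_shape, voxel_size_mm)
  seeds <- atlas_seed_points()
  xdir <- c(SI = 1L, Hp = -1L)  # medial for SI, lateral for Hp
  lab <- array(0L, dim = grid_shape)
  labels <- integer(0)
  boxes <- list()
  next_label <- 1L
  for (rg in regions) {
    s <- mm_to_voxel(seeds[[rg]], voxel_size_mm, origin_mm)
    xs <- sort(s[1] + xdir[[rg]] * (0:(ex[1] - 1L)))
    ys <- s[2] - (ex[2] - 1L) %/% 2L + 0:(ex[2] - 1L)
    zs <- s[3] - (ex[3] - 1L) %/% 2L + 0:(ex[3] - 1L)
    for (hemi in c("L", "R")) {
      name <- paste0(rg, "_", hemi)
      bx <- if (hemi == "L") xs else sort(grid_shape[1] - 1L - xs)
      if (min(bx) < 0L || max(bx) >= grid_shape[1] ||
          min(ys) < 0L || max(ys) >= grid_shape[2] ||
          min(zs) < 0L || max(zs) >= grid_shape[3])
        stop("make_atlas: region ", name, " falls outside the ",
             paste(grid_shape, collapse = "x"), " grid")
      block <- lab[bx + 1L, ys + 1L, zs + 1L]
      if (any(block != 0L)) {
        hit <- names(labels)[match(block[block != 0L][1], labels)]
        stop("make_atlas: region ", name, " overlaps region ", hit)
      }
      lab[bx + 1L, ys + 1L, zs + 1L] <- next_label
      labels[name] <- next_label
      boxes[[name]] <- list(x = bx, y = ys, z = zs)
      next_label <- next_label + 1L
    }
  }
  structure(lab, labels = labels, boxes = boxes,
            voxel_size_mm = as.numeric(voxel_size_mm),
            origin_mm = as.numeric(origin_mm), class = "lff_atlas")
}

#' Logical masks for atlas regions
#'
#' @param atlas an [make_atlas()] volume.
#' @param which label names to extract; default all.
#' @return Named list of logical 3D arrays.
#' @export
region_masks <- function(atlas, which = names(attr(atlas, "labels"))) {
  labs <- attr(atlas, "labels")
  out <- lapply(which, function(nm) {
    if (!nm %in% names(labs)) stop("region_masks: unknown region ", nm)
    array(atlas == labs[[nm]], dim = dim(atlas))
  })
  names(out) <- which
  out
}

#' Simulate band-limited low-frequency fluctuations
#'
#' Gaussian white noise is transformed to the frequency domain, every
#' discrete Fourier coefficient whose (folded) frequency lies outside
#' `band_hz` is set to zero, and the real inverse transform is centred and
#' scaled to unit sample SD. The result is an exactly band-limited,
#' zero-mean, unit-SD series; scaling does not alter its spectral support.
#'
#' @param n_volumes series length.
#' @param tr_s sampling interval, seconds.
#' @param band_hz `(low, high)` passband; `high` must not exceed the
#'   Nyquist frequency `1/(2 tr_s)`.
#' @param n_series number of independent series (columns).
#' @return Numeric vector, or `n_volumes x n_series` matrix.
#' @export
simulate_lff <- function(n_volumes, tr_s, band_hz = c(0.01, 0.08),
                         n_series = 1L) {
  n <- as.integer(n_volumes)
  nyq <- 1 / (2 * tr_s)
  if (band_hz[2] > nyq + 1e-12)
    stop("simulate_lff: band upper bound ", band_hz[2],
         " Hz exceeds Nyquist (", nyq, " Hz)")
  if (band_hz[1] < 0 || band_hz[1] >= band_hz[2])
    stop("simulate_lff: band must satisfy 0 <= low < high")
  w <- matrix(rnorm(n * n_series), n, n_series)
  f <- folded_frequencies(n, tr_s)
  keep <- f >= band_hz[1] - 1e-12 & f <= band_hz[2] + 1e-12
  if (!any(keep)) stop("simulate_lff: no Fourier bin falls inside the band")
  W <- mvfft(w)
  W[!keep, ] <- 0
  x <- Re(mvfft(W, inverse = TRUE)) / n
  x <- sweep(x, 2, colMeans(x))
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  x <- sweep(x, 2, s, "/")
  if (n_series == 1L) drop(x) else x
}

## |f| of each DFT bin of an n-point series sampled every tr_s seconds
folded_frequencies <- function(n, tr_s) {
  k <- 0:(n - 1)
  pmin(k, n - k) / (n * tr_s)
}

## deterministic per-run seed, kept below 2^31
run_seed_for <- function(rng_seed, rat_index, session_index) {
  as.integer((as.numeric(rng_seed) + 7919 * rat_index +
                104729 * session_index) %% 2147483629)
}

outlier_rat_for <- function(config, n_rats, include_drift_outlier) {
  if (!include_drift_outlier) return(NA_integer_)
  set.seed(run_seed_for(config$rng_seed, 0L, 0L))
  sample.int(n_rats, 1L)
}

#' Simulate one rat-session BOLD run with ground truth
#'
#' Each voxel timecourse is
#' `baseline + noise_sd * white + a * noise_sd * s_region + slope * volume +
#' quadratic + physio`, where `s_region` is one band-limited latent signal
#' shared by the left and right boxes of a region and `a` is the coupling
#' amplitude for `(region, hemisphere, condition)` from the config's
#' coupling table (zero in the right hemisphere on days 1 and 3 under the
#' default design). Physiological sinusoids are evaluated at the sampling
#' times with an independent uniform phase per voxel, so above-Nyquist
#' frequencies alias naturally. Dummy volumes are prepended.
#'
#' @param config a [synthetic_config()].
#' @param condition one of `"preop", "d1", "d3", "d9"`.
#' @param rat_id label recorded in the run and ground truth.
#' @param seed optional integer; if given, `set.seed(seed)` first.
#' @param quad_amplitude end-of-run magnitude of an added centred quadratic
#'   baseline (the nonlinear drift planted in the outlier rat); default 0.
#' @param atlas optional precomputed [make_atlas()] matching the config
#'   (rebuilt otherwise).
#' @return `list(run = bold_run, truth = list(...))`; `truth` records the
#'   condition, per region/hemisphere coupling amplitudes, drift and
#'   quadratic coefficients, physiological parameters, the RNG seed, and
#'   the latent LFF series themselves.
#' @export
simulate_run <- function(config, condition, rat_id = "rat01", seed = NULL,
                         quad_amplitude = 0, atlas = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  conds <- unique(config$coupling$condition)
  if (!condition %in% conds)
    stop("simulate_run: unknown condition '", condition, "' (expected one of ",
         paste(conds, collapse = ", "), ")")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(atlas))
    atlas <- make_atlas(config$grid_shape, config$voxel_size_mm,
                        config$region_extent_px, config$regions)
  grid <- config$grid_shape
  nvox <- prod(grid)
  tt <- config$n_dummy + config$n_volumes
  u <- 0:(tt - 1)
  times <- u * config$tr_s

  Y <- matrix(rnorm(nvox * tt, sd = config$noise_sd), nvox, tt)

  latents <- list()
  cpl <- config$coupling[config$coupling$condition == condition, ]
  masks <- region_masks(atlas)
  for (rg in config$regions) {
    s <- simulate_lff(tt, config$tr_s, config$lff_band_hz)
    latents[[rg]] <- s
    for (hemi in c("L", "R")) {
      a <- cpl$amplitude[cpl$region == rg & cpl$hemisphere == hemi]
      if (length(a) != 1L)
        stop("simulate_run: coupling table has no unique entry for (",
             rg, ", ", hemi, ", ", condition, ")")
      if (a > 0) {
        idx <- which(masks[[paste0(rg, "_", hemi)]])
        Y[idx, ] <- Y[idx, ] +
          tcrossprod(rep.int(1, length(idx)), a * config$noise_sd * s)
      }
    }
  }

  slope <- runif(1, config$drift_slope_range[1], config$drift_slope_range[2])
  trend <- config$baseline + slope * u
  quad <- if (quad_amplitude != 0) {
    quad_amplitude * ((u - (tt - 1) / 2) / ((tt - 1) / 2))^2
  } else rep(0, tt)
  Y <- Y + rep(trend + quad, each = nvox)

  physio_truth <- list()
  for (nm in names(config$physio)) {
    comp <- config$physio[[nm]]
    freq <- comp[[1]]; amp <- comp[[2]]
    phase <- runif(nvox, 0, 2 * pi)
    wt <- 2 * pi * freq * times
    Y <- Y + amp * (cos(phase) %o% sin(wt) + sin(phase) %o% cos(wt))
    physio_truth[[nm]] <- list(freq_hz = freq, amplitude = amp,
                               phase_spatially_random = TRUE)
  }

  dim(Y) <- c(grid, tt)
  run <- bold_run(Y, config$voxel_size_mm, tr_s = config$tr_s,
                  n_dummy = config$n_dummy, rat_id = rat_id,
                  condition = condition)
  truth <- list(rat_id = rat_id, condition = condition,
                coupling = cpl[, c("region", "hemisphere", "amplitude")],
                drift_slope = slope,
                quad_amplitude = quad_amplitude,
                physio = physio_truth,
                seed = seed,
                latents = latents)
  list(run = run, truth = truth)
}

#' Simulate a longitudinal cohort and write it to disk
#'
#' Generates `n_rats` rats x 4 sessions (preop, d1, d3, d9 by default).
#' When `include_drift_outlier` is set, exactly one rat (chosen
#' reproducibly from the config seed) has a large quadratic baseline of
#' amplitude `nonlinear_drift_amplitude` added to all of its runs,
#' emulating the animal excluded for large nonlinear baseline drift.
#'
#' Each run gets its own seed derived deterministically from
#' `config$rng_seed` and the (rat, session) index, so the whole cohort is a
#' pure function of `(config, seed)`.
#'
#' @param config a [synthetic_config()].
#' @param n_rats number of rats (>= 1).
#' @param include_drift_outlier plant the nonlinear-drift rat?
#' @param out_dir if non-`NULL`, write one NIfTI per run plus
#'   `manifest.csv` and `ground_truth.json` there; otherwise keep runs in
#'   memory (small grids only).
#' @param conditions session labels, in acquisition order.
#' @param overwrite allow writing into a directory that already contains a
#'   manifest.
#' @return list with `manifest` (data.frame `rat_id, condition, path,
#'   is_outlier`), `truths` (one record per run), and — when `out_dir` is
#'   `NULL` — `runs`, a list of [bold_run()] objects parallel to the
#'   manifest rows.
#' @export
simulate_cohort <- function(config, n_rats, include_drift_outlier = FALSE,
                            out_dir = NULL,
                            conditions = c("preop", "d1", "d3", "d9"),
                            overwrite = FALSE) {
  stopifnot(inherits(config, "synthetic_config"), n_rats >= 1L)
  if (!is.null(out_dir)) {
    manifest_path <- file.path(out_dir, "manifest.csv")
    if (file.exists(manifest_path) && !overwrite)
      stop("simulate_cohort: '", manifest_path,
           "' already exists (output path collision); use overwrite = TRUE")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  atlas <- make_atlas(config$grid_shape, config$voxel_size_mm,
                      config$region_extent_px, config$regions)
  outlier <- outlier_rat_for(config, n_rats, include_drift_outlier)
  rows <- list(); truths <- list(); runs <- list()
  k <- 0L
  for (i in seq_len(n_rats)) {
    rat_id <- sprintf("rat%02d", i)
    for (j in seq_along(conditions)) {
      k <- k + 1L
      sd_ij <- run_seed_for(config$rng_seed, i, j)
      qa <- if (!is.na(outlier) && i == outlier)
        config$nonlinear_drift_amplitude else 0
      sim <- simulate_run(config, conditions[j], rat_id = rat_id,
                          seed = sd_ij, quad_amplitude = qa, atlas = atlas)
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- paste0(rat_id, "_", conditions[j], ".nii.gz")
        write_run(sim$run, file.path(out_dir, path))
      } else {
        runs[[k]] <- sim$run
      }
      sim$truth$is_outlier <- !is.na(outlier) && i == outlier
      truths[[k]] <- sim$truth
      rows[[k]] <- data.frame(rat_id = rat_id, condition = conditions[j],
                              path = path,
                              is_outlier = !is.na(outlier) && i == outlier,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
    jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    list(manifest = manifest, truths = truths)
  } else {
    list(manifest = manifest, truths = truths, runs = runs)
  }
}

#' Simulate Y-maze trials-to-criterion counts
#'
#' Draws integer trial counts per rat and condition from a rounded normal
#' truncated at 1, the minimal generative model consistent with reporting
#' mean +/- SD per session. Defaults follow the published behavioural
#' results: 27 +/- 5 preoperatively, 77 +/- 18 and 70 +/- 14 on days 1 and
#' 3, and recovery (30 +/- 6) by day 9.
#'
#' @param n_rats rats per condition.
#' @param condition_means,condition_sds named numeric vectors (names are
#'   the condition labels, in order).
#' @param seed optional integer seed.
#' @return data.frame `rat_id, condition, trials_to_criterion`; the
#'   condition column is a factor with levels in the given order.
#' @export
simulate_ymaze <- function(n_rats = 18L,
                           condition_means = c(preop = 27, d1 = 77,
                                               d3 = 70, d9 = 30),
                           condition_sds = c(preop = 5, d1 = 18,
                                             d3 = 14, d9 = 6),
                           seed = NULL) {
  stopifnot(all(condition_means >= 1), all(condition_sds >= 0),
            length(condition_means) == length(condition_sds))
  if (!is.null(seed)) set.seed(seed)
  conds <- names(condition_means)
  out <- lapply(seq_along(conds), function(j) {
    raw <- round(rnorm(n_rats, condition_means[j], condition_sds[j]))
    data.frame(rat_id = sprintf("rat%02d", seq_len(n_rats)),
               condition = conds[j],
               trials_to_criterion = as.integer(pmax(1, raw)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$condition <- factor(out$condition, levels = conds)
  out
}
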