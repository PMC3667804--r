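#' Experiment configuration
#'
#' Composes the synthetic-cohort parameterization with the preprocessing,
#' thresholding and behavioural settings of the longitudinal
#' connectivity experiment.
#'
#' @param synthetic a [synthetic_config()].
#' @param n_rats cohort size (the study scanned 18, of which 17 entered
#'   the analysis after drift exclusion).
#' @param include_drift_outlier plant one rat with large nonlinear
#'   baseline drift (see [simulate_cohort()]).
#' @param conditions session labels in order; the first is the baseline
#'   used for count normalization.
#' @param fwhm_mm,cutoff_hz,voxel_scale preprocessing settings (see
#'   [preprocess_run()]).
#' @param quad_threshold drift-exclusion threshold (see
#'   [exclude_drift_runs()]).
#' @param p_threshold voxel-level correlation threshold (default 2.5e-5).
#' @param group_p group-map uncorrected threshold (default 0.001).
#' @param sided sidedness of the voxel threshold.
#' @param seed_rois named list of [roi_spec()] seeds, one per region.
#' @param spectra_rat 1-based index of the rat whose interhemispheric
#'   timecourses/spectra are exported (skipped if excluded).
#' @param spectra_conditions conditions for which spectra are computed.
#' @param ymaze `list(means = ..., sds = ...)` for the behavioural arm
#'   (see [simulate_ymaze()]), or `NULL` to skip it.
#' @param rng_seed master seed; defaults to the synthetic config's seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(synthetic = synthetic_config(),
                              n_rats = 18L,
                              include_drift_outlier = TRUE,
                              conditions = c("preop", "d1", "d3", "d9"),
                              fwhm_mm = 7.8, cutoff_hz = 0.08,
                              voxel_scale = 10, quad_threshold = 2.0,
                              p_threshold = 2.5e-5, group_p = 0.001,
                              sided = "one-sided",
                              seed_rois = NULL,
                              spectra_rat = 1L,
                              spectra_conditions = c("preop", "d9"),
                              ymaze = list(means = c(preop = 27, d1 = 77,
                                                     d3 = 70, d9 = 30),
                                           sds = c(preop = 5, d1 = 18,
                                                   d3 = 14, d9 = 6)),
                              rng_seed = NULL) {
  stopifnot(inherits(synthetic, "synthetic_config"), n_rats >= 1L,
            length(conditions) >= 1L)
  if (is.null(rng_seed)) rng_seed <- synthetic$rng_seed
  synthetic$rng_seed <- as.integer(rng_seed)
  if (is.null(seed_rois))
    seed_rois <- default_seed_rois()[synthetic$regions]
  structure(list(synthetic = synthetic, n_rats = as.integer(n_rats),
                 include_drift_outlier = include_drift_outlier,
                 conditions = conditions, fwhm_mm = fwhm_mm,
                 cutoff_hz = cutoff_hz, voxel_scale = voxel_scale,
                 quad_threshold = quad_threshold,
                 p_threshold = p_threshold, group_p = group_p,
                 sided = sided, seed_rois = seed_rois,
                 spectra_rat = as.integer(spectra_rat),
                 spectra_conditions = spectra_conditions,
                 ymaze = ymaze, rng_seed = as.integer(rng_seed)),
            class = "experiment_config")
}

#' Build an experiment configuration from a YAML file
#'
#' Recognized blocks: `synthetic:` (fields of [synthetic_config()]),
#' `preprocess:` (`fwhm_mm`, `cutoff_hz`, `voxel_scale`,
#' `quad_threshold`), `connectivity:` (`p_threshold`, `group_p`, `sided`),
#' `cohort:` (`n_rats`, `include_drift_outlier`, `conditions`), and
#' `ymaze:` (`means`, `sds`, or `false` to disable).
#'
#' @param path YAML file.
#' @param rng_seed optional seed overriding the file.
#' @return An [experiment_config()].
#' @export
experiment_config_from_yaml <- function(path, rng_seed = NULL) {
  y <- yaml::read_yaml(path)
  syn_args <- y$synthetic
  if (!is.null(syn_args)) {
    for (f in c("grid_shape", "voxel_size_mm", "lff_band_hz",
                "drift_slope_range", "region_extent_px"))
      if (!is.null(syn_args[[f]])) syn_args[[f]] <- unlist(syn_args[[f]])
    if (!is.null(syn_args$physio))
      syn_args$physio <- lapply(syn_args$physio, unlist)
  }
  syn <- do.call(synthetic_config, syn_args %||% list())
  args <- list(synthetic = syn)
  pp <- y$preprocess
  for (f in c("fwhm_mm", "cutoff_hz", "voxel_scale", "quad_threshold"))
    if (!is.null(pp[[f]])) args[[f]] <- pp[[f]]
  cn <- y$connectivity
  for (f in c("p_threshold", "group_p", "sided"))
    if (!is.null(cn[[f]])) args[[f]] <- cn[[f]]
  ch <- y$cohort
  if (!is.null(ch$n_rats)) args$n_rats <- ch$n_rats
  if (!is.null(ch$include_drift_outlier))
    args$include_drift_outlier <- ch$include_drift_outlier
  if (!is.null(ch$conditions)) args$conditions <- unlist(ch$conditions)
  if (!is.null(y$ymaze)) {
    args$ymaze <- if (isFALSE(y$ymaze)) NULL else
      list(means = unlist(y$ymaze$means), sds = unlist(y$ymaze$sds))
  }
  if (!is.null(rng_seed)) args$rng_seed <- rng_seed
  do.call(experiment_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical configuration of the longitudinal study
#'
#' The 18-rat, four-session design (one planted drift-outlier rat, 17
#' analyzed): 120 volumes at TR 2 s after 5 dummy scans, bilateral SI/Hp
#' coupling at 1.2x noise SD abolished in the right hemisphere on days 1
#' and 3 and restored on day 9, FWHM 7.8 mm smoothing at 10x voxel scale,
#' 0.08 Hz low-pass, and a one-sided P < 2.5e-5 voxel threshold at the
#' filtered effective df.
#'
#' At full resolution the grid is the acquisition matrix, 96x96x20 voxels
#' of 0.52x0.52x1 mm. The reduced grid scales the field of view to
#' 64x64x14 voxels (region boxes 6x6x3), which preserves the geometry and
#' statistics of the analysis at about a third of the compute; note that a
#' coarser half-resolution grid is not usable, because there the SI and Hp
#' seed points fall into the same voxel and no disjoint atlas exists.
#'
#' @param reduced use the 64x64x14 grid (default) instead of 96x96x20.
#' @param rng_seed master seed.
#' @param ... overrides passed on to [experiment_config()].
#' @return An [experiment_config()].
#' @export
study_config <- function(reduced = TRUE, rng_seed = 42L, ...) {
  syn <- if (reduced) {
    synthetic_config(grid_shape = c(64L, 64L, 14L),
                     voxel_size_mm = c(50 / 64, 50 / 64, 20 / 14),
                     region_extent_px = c(6L, 6L, 3L),
                     rng_seed = rng_seed)
  } else {
    synthetic_config(rng_seed = rng_seed)
  }
  experiment_config(synthetic = syn, n_rats = 18L,
                    include_drift_outlier = TRUE, rng_seed = rng_seed, ...)
}

#' Run the longitudinal connectivity experiment end to end
#'
#' Simulates (or, via `runs`, ingests) every rat-session run, computes the
#' nonlinear-drift statistic, preprocesses, builds the seed references,
#' correlation maps and supra-threshold counts per atlas region, excludes
#' drift-outlier rats, normalizes counts by each rat's preoperative value,
#' aggregates cohort means, computes Fisher-z group maps per condition,
#' extracts interhemispheric timecourses/spectra for one designated rat,
#' and runs the Y-maze ANOVA arm. Deterministic given the config seed.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-rat progress.
#' @return An object of class `lff_experiment` with elements
#'   `session_results`, `summary`, `cohort_tests`, `exclusions`,
#'   `group_maps`, `spectra`, `ymaze`, `metadata`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  syn <- config$synthetic
  atlas <- make_atlas(syn$grid_shape, syn$voxel_size_mm,
                      syn$region_extent_px, syn$regions)
  masks <- region_masks(atlas)
  rois <- config$seed_rois
  conds <- config$conditions
  baseline_cond <- conds[1]
  outlier <- outlier_rat_for(syn, config$n_rats, config$include_drift_outlier)

  count_rows <- list()
  drift_rows <- list()
  group_rs <- list()   # group_rs[[seed]][[condition]] -> list of r arrays
  spectra_out <- list()
  k <- 0L

  for (i in seq_len(config$n_rats)) {
    rat_id <- sprintf("rat%02d", i)
    if (verbose) message("rat ", i, "/", config$n_rats)
    for (j in seq_along(conds)) {
      qa <- if (!is.na(outlier) && i == outlier)
        syn$nonlinear_drift_amplitude else 0
      sim <- simulate_run(syn, conds[j], rat_id = rat_id,
                          seed = run_seed_for(syn$rng_seed, i, j),
                          quad_amplitude = qa, atlas = atlas)
      run <- drop_dummies(sim$run)
      ds <- drift_statistic(run)
      drift_rows[[length(drift_rows) + 1L]] <-
        data.frame(rat_id = rat_id, rat_index = i, condition = conds[j],
                   statistic = ds$statistic, stringsAsFactors = FALSE)
      pre <- preprocess_run(run, config$fwhm_mm, config$cutoff_hz,
                            config$voxel_scale)
      for (rg in names(rois)) {
        ref <- seed_reference(pre, rois[[rg]])
        cmap <- correlation_map(pre, ref, config$p_threshold,
                                config$cutoff_hz, config$sided,
                                seed = rois[[rg]])
        for (hemi in c("L", "R")) {
          lbl <- paste0(rg, "_", hemi)
          k <- k + 1L
          count_rows[[k]] <- data.frame(
            rat_id = rat_id, rat_index = i, condition = conds[j],
            seed = rg, region = lbl,
            count = count_significant(cmap, masks[[lbl]]),
            stringsAsFactors = FALSE)
        }
        group_rs[[rg]][[conds[j]]][[i]] <- cmap$r
      }
      if (i == config$spectra_rat && conds[j] %in% config$spectra_conditions) {
        spectra_out[[conds[j]]] <- interhemispheric_spectra(
          run, pre, masks, syn$regions, config$cutoff_hz)
      }
    }
  }

  drift_table <- do.call(rbind, drift_rows)
  excluded_idx <- sort(unique(
    drift_table$rat_index[drift_table$statistic > config$quad_threshold]))
  drift_table$excluded <- drift_table$rat_index %in% excluded_idx

  counts <- do.call(rbind, count_rows)
  ## per-seed totals over both hemispheres
  tot <- stats::aggregate(count ~ rat_id + rat_index + condition + seed,
                          data = counts, FUN = sum)
  tot$region <- paste0(tot$seed, "_total")
  counts <- rbind(counts, tot[, names(counts)])

  pre_counts <- counts[counts$condition == baseline_cond,
                       c("rat_id", "seed", "region", "count")]
  names(pre_counts)[4] <- "preop_count"
  counts <- merge(counts, pre_counts, by = c("rat_id", "seed", "region"),
                  sort = FALSE)
  counts$normalized <- ifelse(counts$preop_count > 0,
                              counts$count / counts$preop_count, NA_real_)
  counts$analyzed <- !(counts$rat_index %in% excluded_idx)
  counts <- counts[order(counts$rat_index,
                         match(counts$condition, conds),
                         counts$seed, counts$region), ]
  rownames(counts) <- NULL

  ana <- counts[counts$analyzed, ]
  summary_tab <- stats::aggregate(
    cbind(count, normalized) ~ condition + seed + region, data = ana,
    FUN = function(v) c(mean = mean(v), sd = sd(v)), na.action = stats::na.omit)
  summary_tab <- data.frame(
    condition = summary_tab$condition, seed = summary_tab$seed,
    region = summary_tab$region,
    mean_count = summary_tab$count[, "mean"],
    sd_count = summary_tab$count[, "sd"],
    mean_normalized = summary_tab$normalized[, "mean"],
    sd_normalized = summary_tab$normalized[, "sd"],
    stringsAsFactors = FALSE)
  summary_tab <- summary_tab[order(summary_tab$seed, summary_tab$region,
                                   match(summary_tab$condition, conds)), ]
  rownames(summary_tab) <- NULL

  ## paired comparison of each postoperative session against baseline
  cohort_tests <- list()
  for (rg in names(rois)) {
    for (cd in setdiff(conds, baseline_cond)) {
      v <- ana$normalized[ana$seed == rg &
                            ana$region == paste0(rg, "_total") &
                            ana$condition == cd]
      v <- v[is.finite(v)]
      if (length(v) >= 3L && sd(v) > 0) {
        tt <- t.test(v, mu = 1)
        cohort_tests[[length(cohort_tests) + 1L]] <- data.frame(
          seed = rg, condition = cd, mean_normalized = mean(v),
          t = unname(tt$statistic), p = tt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  cohort_tests <- if (length(cohort_tests)) do.call(rbind, cohort_tests)
    else NULL

  analyzed_idx <- setdiff(seq_len(config$n_rats), excluded_idx)
  group_maps <- list()
  for (rg in names(group_rs)) {
    for (cd in names(group_rs[[rg]])) {
      rs <- group_rs[[rg]][[cd]][analyzed_idx]
      rs <- rs[!vapply(rs, is.null, TRUE)]
      if (length(rs) >= 3L)
        group_maps[[rg]][[cd]] <- group_tmap(rs, config$group_p)
    }
  }

  ymaze_res <- NULL
  if (!is.null(config$ymaze)) {
    tab <- simulate_ymaze(config$n_rats, config$ymaze$means,
                          config$ymaze$sds,
                          seed = run_seed_for(syn$rng_seed, 104729L, 7L))
    ymaze_res <- c(list(table = tab), ymaze_anova(tab))
  }

  eff_df <- effective_df(syn$n_volumes, syn$tr_s, config$cutoff_hz)
  metadata <- list(
    package_version = as.character(packageVersion("lffconn")),
    rng_seed = syn$rng_seed,
    n_rats = config$n_rats,
    n_analyzed = length(analyzed_idx),
    excluded_rats = sprintf("rat%02d", excluded_idx),
    conditions = conds,
    grid_shape = syn$grid_shape,
    voxel_size_mm = syn$voxel_size_mm,
    n_volumes = syn$n_volumes, n_dummy = syn$n_dummy, tr_s = syn$tr_s,
    fwhm_mm = config$fwhm_mm, voxel_scale = config$voxel_scale,
    cutoff_hz = config$cutoff_hz,
    quad_threshold = config$quad_threshold,
    p_threshold = config$p_threshold,
    group_p = config$group_p, sided = config$sided,
    effective_df = eff_df,
    r_critical = r_critical(config$p_threshold, eff_df, config$sided),
    group_test = "one-sample t of Fisher z(r) against 0 (r = 1 not testable)")

  structure(list(session_results = counts, summary = summary_tab,
                 cohort_tests = cohort_tests,
                 exclusions = drift_table,
                 group_maps = group_maps, spectra = spectra_out,
                 ymaze = ymaze_res, atlas = atlas, metadata = metadata),
            class = "lff_experiment")
}

## Fig-3-style product for one run: percent-signal-change region-mean
## timecourses for both hemispheres, their amplitude spectra, and the
## homotopic correlation. `raw` supplies the baseline mean; `pre` the
## preprocessed data.
interhemispheric_spectra <- function(raw, pre, masks, regions, cutoff_hz) {
  d <- dim(pre$data)
  Yp <- matrix(pre$data, prod(d[1:3]), d[4])
  Yr <- matrix(raw$data, prod(d[1:3]), dim(raw$data)[4])
  out <- list()
  for (rg in regions) {
    res <- list()
    for (hemi in c("L", "R")) {
      idx <- which(masks[[paste0(rg, "_", hemi)]])
      m0 <- mean(colMeans(Yr[idx, , drop = FALSE]))
      tc <- colMeans(Yp[idx, , drop = FALSE])
      psc <- percent_signal_change(tc, reference_mean = m0)
      res[[hemi]] <- list(
        timecourse = psc,
        spectrum = amplitude_spectrum(psc, pre$tr_s,
                                      source = paste0(rg, "_", hemi)))
    }
    res$r <- homotopic_correlation(res$L$timecourse, res$R$timecourse)
    out[[rg]] <- res
  }
  out
}

#' @export
print.lff_experiment <- function(x, ...) {
  md <- x$metadata
  cat("<lff_experiment>\n")
  cat(sprintf("  %d rats (%d analyzed, excluded: %s), conditions: %s\n",
              md$n_rats, md$n_analyzed,
              if (length(md$excluded_rats)) paste(md$excluded_rats,
                                                  collapse = ", ") else "none",
              paste(md$conditions, collapse = ", ")))
  cat(sprintf("  grid %s, %d volumes at TR %g s; threshold p < %g at df %.1f (r >= %.3f)\n",
              paste(md$grid_shape, collapse = "x"), md$n_volumes, md$tr_s,
              md$p_threshold, md$effective_df, md$r_critical))
  cat("  cohort mean normalized counts:\n")
  s <- x$summary[x$summary$region %in% paste0(x$summary$seed, "_total"), ]
  print(s[, c("seed", "condition", "mean_normalized", "sd_normalized")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' One-way ANOVA of Y-maze trials-to-criterion
#'
#' Omnibus one-way ANOVA across conditions plus unadjusted two-sample
#' t contrasts of each postoperative session against the first
#' (preoperative) condition.
#'
#' @param table data.frame as from [simulate_ymaze()] with columns
#'   `condition` and `trials_to_criterion`.
#' @return list with `F`, `p`, `anova` (the full table), and `contrasts`
#'   (data.frame `condition, diff, t, p`).
#' @export
ymaze_anova <- function(table) {
  stopifnot(all(c("condition", "trials_to_criterion") %in% names(table)))
  table$condition <- factor(table$condition,
                            levels = unique(as.character(table$condition)))
  sizes <- table(table$condition)
  if (length(sizes) < 2L)
    stop("ymaze_anova: at least 2 conditions are required")
  if (any(sizes < 2L))
    stop("ymaze_anova: condition(s) with fewer than 2 rats: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  y <- table$trials_to_criterion
  if (var(y) == 0) {
    fstat <- 0; pval <- 1; av <- NULL
  } else {
    fit <- aov(trials_to_criterion ~ condition, data = table)
    av <- summary(fit)[[1]]
    fstat <- av[["F value"]][1]
    pval <- av[["Pr(>F)"]][1]
  }
  ref <- levels(table$condition)[1]
  contrasts <- lapply(levels(table$condition)[-1], function(cd) {
    a <- y[table$condition == ref]
    b <- y[table$condition == cd]
    if (var(a) == 0 && var(b) == 0) {
      data.frame(condition = cd, diff = mean(b) - mean(a),
                 t = if (mean(b) == mean(a)) 0 else Inf,
                 p = if (mean(b) == mean(a)) 1 else 0,
                 stringsAsFactors = FALSE)
    } else {
      tt <- t.test(b, a, var.equal = TRUE)
      data.frame(condition = cd, diff = mean(b) - mean(a),
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  list(F = fstat, p = pval, anova = av,
       contrasts = do.call(rbind, contrasts))
}

#' Write an experiment bundle to disk
#'
#' Writes the Tables-analogue CSVs, exclusion table, Y-maze outputs,
#' group t/p/significance maps as NIfTI, spectra as CSV, a JSON metadata
#' file recording every threshold and seed, and a plain-text log.
#'
#' @param bundle an `lff_experiment` from [run_experiment()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty existing directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir, force = FALSE) {
  if (!inherits(bundle, "lff_experiment") ||
      is.null(bundle$session_results) || !nrow(bundle$session_results))
    stop("write_report: `bundle` is not a complete lff_experiment")
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("write_report: '", out_dir, "' exists and is not empty; ",
         "use force = TRUE to overwrite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write.csv(df, file.path(out_dir, name),
                                    row.names = FALSE)
  w(bundle$session_results, "session_results.csv")
  w(bundle$summary, "cohort_summary.csv")
  w(bundle$exclusions, "exclusions.csv")
  if (!is.null(bundle$cohort_tests)) w(bundle$cohort_tests,
                                       "cohort_tests.csv")
  if (!is.null(bundle$ymaze)) {
    w(bundle$ymaze$table, "ymaze.csv")
    jsonlite::write_json(
      list(F = bundle$ymaze$F, p = bundle$ymaze$p,
           contrasts = bundle$ymaze$contrasts),
      file.path(out_dir, "ymaze_anova.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  vs <- bundle$metadata$voxel_size_mm
  for (rg in names(bundle$group_maps)) {
    for (cd in names(bundle$group_maps[[rg]])) {
      gm <- bundle$group_maps[[rg]][[cd]]
      for (what in c("t", "p", "significant")) {
        arr <- gm[[what]]
        arr[!is.finite(arr)] <- 0
        img <- RNifti::asNifti(arr * 1)
        RNifti::pixdim(img) <- vs
        RNifti::writeNifti(img, file.path(
          out_dir, sprintf("group_%s_%s_%s.nii.gz", rg, cd, what)))
      }
    }
  }
  for (cd in names(bundle$spectra)) {
    for (rg in names(bundle$spectra[[cd]])) {
      sp <- bundle$spectra[[cd]][[rg]]
      tcs <- data.frame(volume = seq_along(sp$L$timecourse),
                        left_pct = sp$L$timecourse,
                        right_pct = sp$R$timecourse)
      w(tcs, sprintf("timecourse_%s_%s.csv", rg, cd))
      spec <- data.frame(frequency = sp$L$spectrum$frequency,
                         left_amplitude = sp$L$spectrum$amplitude,
                         right_amplitude = sp$R$spectrum$amplitude)
      w(spec, sprintf("spectrum_%s_%s.csv", rg, cd))
    }
  }
  jsonlite::write_json(bundle$metadata, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- c(
    paste0("lffconn ", bundle$metadata$package_version),
    paste0("seed: ", bundle$metadata$rng_seed),
    paste0("rats: ", bundle$metadata$n_rats, " (analyzed ",
           bundle$metadata$n_analyzed, ")"),
    paste0("excluded: ", paste(bundle$metadata$excluded_rats,
                               collapse = ", ")),
    paste0("written: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
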