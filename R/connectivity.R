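#' Seed reference timecourse
#'
#' Mean across the ROI voxels of their (already preprocessed) timecourses.
#' No variance normalization is applied: Pearson correlation is invariant
#' to affine rescaling of the reference.
#'
#' @param run a preprocessed [bold_run()].
#' @param roi a [roi_spec()].
#' @return Numeric reference timecourse of length `dim(run$data)[4]`.
#' @export
seed_reference <- function(run, roi) {
  stopifnot(inherits(run, "bold_run"), inherits(roi, "roi_spec"))
  vox <- roi_to_voxels(roi, run)
  d <- dim(run$data)
  Y <- matrix(run$data, prod(d[1:3]), d[4])
  tc <- Y[voxel_linear_index(vox, d[1:3]), , drop = FALSE]
  if (all(apply(tc, 1, var) == 0))
    stop("seed_reference: every voxel of seed '", roi$name,
         "' has zero variance (degenerate seed)")
  colMeans(tc)
}

#' Effective degrees of freedom of a low-pass filtered series
#'
#' After ideal low-pass filtering, only the fraction `2 * cutoff * TR` of
#' the spectrum is retained, so a series of `n` samples carries about
#' `n * 2 * cutoff * TR` independent values; two are spent estimating the
#' correlation, giving `df = n * 2 * cutoff_hz * tr_s - 2`. For the study
#' settings (n = 120, TR = 2 s, cutoff = 0.08 Hz) this is 36.4.
#'
#' @param n_timepoints number of (post-dummy) volumes.
#' @param tr_s repetition time, seconds.
#' @param cutoff_hz low-pass cutoff, Hz (must be below Nyquist).
#' @return Effective degrees of freedom (>= 3, else an error: the series
#'   is too short or the band too narrow for inference).
#' @export
effective_df <- function(n_timepoints, tr_s, cutoff_hz) {
  nyq <- 1 / (2 * tr_s)
  if (cutoff_hz >= nyq - 1e-12)
    stop("effective_df: cutoff must be below the Nyquist frequency (",
         nyq, " Hz)")
  df <- n_timepoints * 2 * cutoff_hz * tr_s - 2
  if (df < 3)
    stop("effective_df: effective df ", round(df, 2), " < 3; the series is ",
         "too short or the band too narrow")
  df
}

#' Critical correlation for a given tail probability
#'
#' Inverts the t statistic `t = r * sqrt(df / (1 - r^2))`: returns the
#' correlation whose upper-tail probability under the t distribution with
#' `effective_df` degrees of freedom equals `p_threshold`. One-sided
#' positive by default (synchronized, i.e. positively correlated, voxels
#' are counted); the two-sided variant uses `p/2` per tail.
#'
#' @param p_threshold tail probability in (0, 1).
#' @param effective_df degrees of freedom (>= 3).
#' @param sided `"one-sided"` (default) or `"two-sided"`.
#' @return Critical correlation value.
#' @export
r_critical <- function(p_threshold, effective_df,
                       sided = c("one-sided", "two-sided")) {
  sided <- match.arg(sided)
  stopifnot(p_threshold > 0, p_threshold < 1, effective_df >= 3)
  q <- if (sided == "one-sided") 1 - p_threshold else 1 - p_threshold / 2
  tcrit <- qt(q, df = effective_df)
  tcrit / sqrt(tcrit^2 + effective_df)
}

#' Voxel-wise correlation map against a reference timecourse
#'
#' Pearson correlation at lag 0 between every voxel timecourse and the
#' reference. Voxels with zero-variance timecourses are marked undefined
#' (`NA`), never 0. The map carries the effective degrees of freedom and
#' the critical correlation used downstream for thresholding.
#'
#' @param run a preprocessed [bold_run()].
#' @param reference numeric timecourse, length `dim(run$data)[4]`, with
#'   positive variance.
#' @param p_threshold voxel-level tail probability (default 2.5e-5), or
#'   `NULL` for a plain correlation map without threshold information
#'   (e.g. for series too short for the effective-df correction).
#' @param cutoff_hz the low-pass cutoff that was applied to the data, used
#'   for the effective-df correction.
#' @param sided sidedness of the threshold (see [r_critical()]).
#' @param seed optional [roi_spec()] recorded in the result.
#' @return An object of class `correlation_map`: list with `r` (3D array
#'   in [-1, 1] with `NA` for undefined voxels), `effective_df`,
#'   `p_threshold`, `r_critical`, `sided`, `seed`.
#' @export
correlation_map <- function(run, reference, p_threshold = 2.5e-5,
                            cutoff_hz = 0.08,
                            sided = c("one-sided", "two-sided"),
                            seed = NULL) {
  sided <- match.arg(sided)
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  if (length(reference) != d[4])
    stop("correlation_map: reference length ", length(reference),
         " != run length ", d[4])
  if (var(reference) == 0)
    stop("correlation_map: reference timecourse has zero variance ",
         "(degenerate seed)")
  Y <- matrix(run$data, prod(d[1:3]), d[4])
  Yc <- Y - rowMeans(Y)
  refc <- reference - mean(reference)
  num <- drop(Yc %*% refc)
  den <- sqrt(rowSums(Yc^2) * sum(refc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  df <- if (is.null(p_threshold)) NA_real_
        else effective_df(d[4], run$tr_s, cutoff_hz)
  structure(list(r = array(r, dim = d[1:3]),
                 effective_df = df,
                 p_threshold = if (is.null(p_threshold)) NA_real_
                               else p_threshold,
                 r_critical = if (is.null(p_threshold)) NA_real_
                              else r_critical(p_threshold, df, sided),
                 sided = sided, seed = seed,
                 rat_id = run$rat_id, condition = run$condition),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf(
    "<correlation_map> %s / %s: %s grid, df = %.1f, r >= %.3f at p < %g (%s)\n",
    x$rat_id, x$condition, paste(dim(x$r), collapse = "x"),
    x$effective_df, x$r_critical, x$p_threshold, x$sided))
  invisible(x)
}

#' Count supra-threshold voxels within a mask
#'
#' Number of voxels inside the mask whose correlation is at least the
#' map's critical value (ties count as significant). Undefined voxels are
#' never counted.
#'
#' @param map a [correlation_map()].
#' @param mask logical 3D array on the map's grid.
#' @return Non-negative integer count.
#' @export
count_significant <- function(map, mask) {
  stopifnot(inherits(map, "correlation_map"))
  if (!is.finite(map$r_critical))
    stop("count_significant: map carries no threshold (built with ",
         "p_threshold = NULL)")
  if (!identical(dim(mask), dim(map$r)))
    stop("count_significant: mask dimensions ",
         paste(dim(mask), collapse = "x"), " do not match map grid ",
         paste(dim(map$r), collapse = "x"))
  r <- map$r[mask]
  sum(r >= map$r_critical, na.rm = TRUE)
}

#' Normalize per-session voxel counts by the preoperative count
#'
#' @param counts named numeric vector of supra-threshold counts per
#'   region for one session.
#' @param preop_counts named numeric vector of the same rat's preoperative
#'   counts (same names).
#' @return data.frame `region, count, preop_count, normalized`; the
#'   normalized value is `NA` (undefined, excluded from means) where the
#'   preoperative count is 0.
#' @export
normalize_counts <- function(counts, preop_counts) {
  regions <- names(counts)
  if (!setequal(regions, names(preop_counts)))
    stop("normalize_counts: region names of `counts` and `preop_counts` ",
         "differ")
  pre <- preop_counts[regions]
  data.frame(region = regions,
             count = as.numeric(counts),
             preop_count = as.numeric(pre),
             normalized = ifelse(pre > 0, as.numeric(counts) / pre,
                                 NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group-level one-sample map from individual correlation maps
#'
#' Each rat's correlation map is Fisher z-transformed and a voxel-wise
#' one-sample t test of z against 0 computed across rats, with one-sided
#' uncorrected p values and a binary significance map at `p_threshold`.
#' (A one-sample test of the raw correlations against 1 is not computable
#' — r = 1 is the boundary of the parameter space — so the group test is
#' performed on the z scale against 0; this choice is recorded in the
#' result.) Voxels that are undefined in any map, or that have zero
#' variance across rats, are flagged undefined rather than given infinite
#' statistics.
#'
#' @param maps list of at least 3 [correlation_map()] objects (or bare 3D
#'   correlation arrays) on identical grids.
#' @param p_threshold group-level uncorrected threshold (default 0.001).
#' @return list with `t`, `p`, `significant` (3D arrays), `n`,
#'   `p_threshold`, and `test` (a description of the statistic).
#' @export
group_tmap <- function(maps, p_threshold = 0.001) {
  rs <- lapply(maps, function(m) if (inherits(m, "correlation_map")) m$r else m)
  n <- length(rs)
  if (n < 3L)
    stop("group_tmap: at least 3 maps are required, got ", n)
  dims <- lapply(rs, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("group_tmap: maps are not on identical grids")
  eps <- 1e-12
  zs <- vapply(rs, function(r) atanh(pmin(pmax(r, -1 + eps), 1 - eps)),
               rs[[1]])
  dim(zs) <- c(prod(dims[[1]]), n)
  mu <- rowMeans(zs)
  ss <- sqrt(rowSums((zs - mu)^2) / (n - 1))
  ## sd = 0 with mean 0 carries no evidence (t = 0, p = 1); sd = 0 with a
  ## non-zero mean is flagged undefined rather than given an infinite t
  tstat <- ifelse(is.finite(mu) & is.finite(ss) & ss > 0,
                  mu / (ss / sqrt(n)),
                  ifelse(is.finite(mu) & mu == 0, 0, NA_real_))
  pval <- pt(tstat, df = n - 1, lower.tail = FALSE)
  pval[is.finite(mu) & is.finite(ss) & ss == 0 & mu == 0] <- 1
  sig <- !is.na(pval) & pval < p_threshold
  shape <- dims[[1]]
  list(t = array(tstat, shape), p = array(pval, shape),
       significant = array(sig, shape), n = n, p_threshold = p_threshold,
       test = "one-sample t of Fisher z(r) against 0, one-sided, uncorrected")
}

#' Monte-Carlo null calibration of the correlation threshold
#'
#' Generates pairs of independent white-noise series, low-pass filters both
#' with [lowpass()], and measures the one-sided exceedance rate of
#' `r_critical(p, effective_df)` for each requested `p`. Under a correct
#' effective-df correction the observed rate matches the nominal tail
#' probability to within binomial sampling error.
#'
#' @param n_pairs number of independent series pairs.
#' @param p_thresholds tail probabilities to calibrate.
#' @param n_timepoints,tr_s,cutoff_hz series length, sampling interval and
#'   filter cutoff (defaults: the study settings).
#' @param seed optional integer seed.
#' @param chunk pairs simulated per block (memory control).
#' @return data.frame `p, r_critical, exceedances, fraction, se` where
#'   `se = sqrt(p (1 - p) / n_pairs)` is the binomial SE of the nominal
#'   rate.
#' @export
null_calibration <- function(n_pairs, p_thresholds = c(0.01, 0.001),
                             n_timepoints = 120L, tr_s = 2,
                             cutoff_hz = 0.08, seed = NULL,
                             chunk = 20000L) {
  if (!is.null(seed)) set.seed(seed)
  df <- effective_df(n_timepoints, tr_s, cutoff_hz)
  rc <- vapply(p_thresholds, r_critical, 0, effective_df = df)
  exceed <- numeric(length(rc))
  done <- 0L
  while (done < n_pairs) {
    m <- min(chunk, n_pairs - done)
    A <- lowpass(matrix(rnorm(n_timepoints * m), n_timepoints, m),
                 cutoff_hz, tr_s)
    B <- lowpass(matrix(rnorm(n_timepoints * m), n_timepoints, m),
                 cutoff_hz, tr_s)
    A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
    r <- colSums(A * B) / sqrt(colSums(A^2) * colSums(B^2))
    for (i in seq_along(rc)) exceed[i] <- exceed[i] + sum(r >= rc[i])
    done <- done + m
  }
  data.frame(p = p_thresholds, r_critical = rc, exceedances = exceed,
             fraction = exceed / n_pairs,
             se = sqrt(p_thresholds * (1 - p_thresholds) / n_pairs))
}
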