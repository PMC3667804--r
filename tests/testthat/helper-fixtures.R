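## Small-grid configurations used across tests. 32x32x8 is the smallest
## grid on which the SI and Hp seed points still separate into disjoint
## atlas boxes; 24x24x6 works for SI alone.
tiny_syn <- function(...) {
  synthetic_config(grid_shape = c(32L, 32L, 8L),
                   voxel_size_mm = c(50 / 32, 50 / 32, 2.5),
                   region_extent_px = c(3L, 3L, 2L), rng_seed = 7L, ...)
}

coarse_si_syn <- function(...) {
  synthetic_config(grid_shape = c(24L, 24L, 6L),
                   voxel_size_mm = c(50 / 24, 50 / 24, 20 / 6),
                   region_extent_px = c(2L, 2L, 2L), regions = "SI",
                   rng_seed = 3L, ...)
}

## independent brute-force oracle: dense separable-Gaussian smoothing with
## nearest-edge replication, kernel truncated at 4 sigma and renormalized
dense_smooth_oracle <- function(vol, sigma_vox) {
  d <- dim(vol)
  g1 <- function(sigma) {
    r <- max(1L, ceiling(4 * sigma))
    w <- exp(-((-r):r)^2 / (2 * sigma^2))
    list(off = (-r):r, w = w / sum(w))
  }
  ks <- lapply(sigma_vox, g1)
  out <- array(0, d)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in seq_along(ks[[1]]$off)) for (b in seq_along(ks[[2]]$off))
      for (cc in seq_along(ks[[3]]$off)) {
        acc <- acc + ks[[1]]$w[a] * ks[[2]]$w[b] * ks[[3]]$w[cc] *
          vol[clamp(i + ks[[1]]$off[a], d[1]),
              clamp(j + ks[[2]]$off[b], d[2]),
              clamp(k + ks[[3]]$off[cc], d[3])]
      }
    out[i, j, k] <- acc
  }
  out
}

## wrap a 3D volume (plus a zero second volume) as a bold_run for smoothing
as_smooth_run <- function(vol, voxel_size_mm) {
  arr <- array(0, c(dim(vol), 2))
  arr[, , , 1] <- vol
  bold_run(arr, voxel_size_mm, tr_s = 2, n_dummy = 0L)
}

## region-mean timecourse of a preprocessed run
mask_mean_tc <- function(run, mask) {
  d <- dim(run$data)
  Y <- matrix(run$data, prod(d[1:3]), d[4])
  colMeans(Y[which(mask), , drop = FALSE])
}
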