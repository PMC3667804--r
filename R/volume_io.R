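#' @importFrom stats coef cor fft lm mvfft pt qt residuals rnorm runif sd
#'   t.test var aov
#' @importFrom utils packageVersion read.csv write.csv
NULL

#' Construct a BOLD run object
#'
#' A `bold_run` holds one rat-session 4D time series together with its grid
#' geometry: voxel size, the atlas-space position of voxel `(0,0,0)`, the
#' repetition time, and the number of leading dummy (steady-state) volumes
#' still present in the data.
#'
#' Coordinate conventions: voxel indices are 0-based, and
#' `mm = origin_mm + index * voxel_size_mm` gives the centre of a voxel in
#' atlas (Paxinos-style) millimetre space. The default origin centres the
#' grid on the atlas origin, so a symmetric grid mirrors exactly across
#' `x = 0`.
#'
#' @param data 4D numeric array, dimensions `(x, y, z, t)`, in signal units.
#' @param voxel_size_mm length-3 positive numeric, mm per voxel along x/y/z.
#' @param origin_mm length-3 numeric; atlas mm coordinate of voxel
#'   `(0,0,0)`'s centre. Default centres the grid at the atlas origin.
#' @param tr_s repetition time in seconds (sampling interval of the series).
#' @param n_dummy number of leading dummy volumes included in `data`.
#' @param rat_id,condition labels carried through the pipeline.
#' @return An object of class `bold_run`.
#' @seealso [read_run()], [write_run()], [drop_dummies()]
#' @export
bold_run <- function(data, voxel_size_mm, origin_mm = NULL, tr_s,
                     n_dummy = 0L, rat_id = NA_character_,
                     condition = NA_character_) {
  if (length(dim(data)) != 4L)
    stop("bold_run: `data` must be a 4D (x, y, z, t) array, got ",
         length(dim(data)), " dimensions")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("bold_run: `voxel_size_mm` must be 3 positive reals")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("bold_run: `tr_s` must be a positive scalar")
  if (n_dummy < 0) stop("bold_run: `n_dummy` must be non-negative")
  grid <- dim(data)[1:3]
  if (is.null(origin_mm)) origin_mm <- grid_origin(grid, voxel_size_mm)
  if (dim(data)[4] < n_dummy + 2L)
    stop("bold_run: time dimension (", dim(data)[4],
         ") must be at least n_dummy + 2 = ", n_dummy + 2L)
  structure(list(data = data,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_mm = as.numeric(origin_mm),
                 tr_s = as.numeric(tr_s),
                 n_dummy = as.integer(n_dummy),
                 rat_id = rat_id, condition = condition),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %s / %s: %dx%dx%d voxels x %d volumes (TR %g s, %d dummy)\n",
              x$rat_id, x$condition, d[1], d[2], d[3], d[4], x$tr_s, x$n_dummy))
  invisible(x)
}

#' Atlas-space origin of a centred grid
#'
#' Returns the mm coordinate of voxel `(0,0,0)` such that the grid is
#' symmetric about the atlas origin: voxel centres sit at
#' `voxel_size * (i - (n-1)/2)`.
#'
#' @param grid_shape length-3 integer grid dimensions.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @return length-3 numeric origin in mm.
#' @export
grid_origin <- function(grid_shape, voxel_size_mm) {
  -as.numeric(voxel_size_mm) * (as.numeric(grid_shape) - 1) / 2
}

#' Convert between atlas mm coordinates and 0-based voxel indices
#'
#' `mm_to_voxel` returns the index of the voxel containing a point:
#' the affine is inverted to a continuous index and the nearest voxel
#' centre taken by `floor(c + 0.5)` (each voxel owns the half-open mm
#' interval centred on it). `voxel_to_mm` is the exact inverse on voxel
#' centres.
#'
#' @param mm,voxel length-3 numeric coordinate (mm) or 0-based voxel index.
#' @param voxel_size_mm,origin_mm grid geometry as in [bold_run()].
#' @return length-3 integer voxel index, or length-3 numeric mm coordinate.
#' @export
mm_to_voxel <- function(mm, voxel_size_mm, origin_mm) {
  as.integer(floor((as.numeric(mm) - origin_mm) / voxel_size_mm + 0.5))
}

#' @rdname mm_to_voxel
#' @export
voxel_to_mm <- function(voxel, voxel_size_mm, origin_mm) {
  origin_mm + as.numeric(voxel) * voxel_size_mm
}

#' Define a seed region of interest
#'
#' A seed ROI is a small in-plane pixel block (the conventional 2x2 pixels,
#' one slice) anchored at an atlas-space coordinate, used to build the
#' low-frequency reference timecourse for correlation mapping.
#'
#' `x_dir` controls the in-plane direction in which the block extends from
#' the anchor voxel along x (+1 medially for the default left-SI seed, -1
#' for the left-hippocampus seed, whose anatomical box in the toy atlas lies
#' lateral to its seed point); y and z always extend in the positive
#' direction. This keeps the default seed blocks inside their atlas regions.
#'
#' @param name label for the ROI.
#' @param center_mm length-3 atlas coordinate (mm) of the anchor point.
#' @param extent_px length-3 positive integer block extent in voxels
#'   (default 2x2 in-plane, 1 slice).
#' @param hemisphere `"L"` or `"R"`.
#' @param region `"SI"` (primary somatosensory cortex) or `"Hp"`
#'   (hippocampus).
#' @param x_dir +1 or -1; direction of block growth along x.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, center_mm, extent_px = c(2L, 2L, 1L),
                     hemisphere = c("L", "R"), region = c("SI", "Hp"),
                     x_dir = 1L) {
  hemisphere <- match.arg(hemisphere)
  region <- match.arg(region)
  extent_px <- as.integer(extent_px)
  if (length(extent_px) != 3L || any(extent_px < 1L))
    stop("roi_spec: `extent_px` must be 3 integers >= 1")
  if (!x_dir %in% c(-1L, 1L)) stop("roi_spec: `x_dir` must be +1 or -1")
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 extent_px = extent_px, hemisphere = hemisphere,
                 region = region, x_dir = as.integer(x_dir)),
            class = "roi_spec")
}

#' Default seed ROIs at the standard atlas coordinates
#'
#' Left primary somatosensory cortex at (-4.2, -2.2, -0.2) mm and left
#' hippocampus at (-4.8, -2.4, -0.4) mm, each a 2x2-pixel single-slice
#' block.
#'
#' @return Named list of two [roi_spec()] objects (`SI`, `Hp`).
#' @export
default_seed_rois <- function() {
  list(SI = roi_spec("SI_L_seed", c(-4.2, -2.2, -0.2), hemisphere = "L",
                     region = "SI", x_dir = 1L),
       Hp = roi_spec("Hp_L_seed", c(-4.8, -2.4, -0.4), hemisphere = "L",
                     region = "Hp", x_dir = -1L))
}

#' Resolve an ROI to voxel indices on a grid
#'
#' Maps the ROI anchor to its containing voxel (floor after affine
#' inversion, see [mm_to_voxel()]) and returns the `extent_px` block with
#' that voxel as corner.
#'
#' @param roi a [roi_spec()].
#' @param grid_shape length-3 grid dimensions, or a [bold_run()] from which
#'   geometry is taken.
#' @param voxel_size_mm,origin_mm grid geometry (ignored when `grid_shape`
#'   is a `bold_run`).
#' @return Integer matrix with one row per voxel and columns `x, y, z`
#'   (0-based indices).
#' @export
roi_to_voxels <- function(roi, grid_shape, voxel_size_mm = NULL,
                          origin_mm = NULL) {
  if (inherits(grid_shape, "bold_run")) {
    run <- grid_shape
    grid_shape <- dim(run$data)[1:3]
    voxel_size_mm <- run$voxel_size_mm
    origin_mm <- run$origin_mm
  }
  if (is.null(origin_mm)) origin_mm <- grid_origin(grid_shape, voxel_size_mm)
  anchor <- mm_to_voxel(roi$center_mm, voxel_size_mm, origin_mm)
  if (any(anchor < 0L) || any(anchor >= grid_shape))
    stop("roi_to_voxels: centre of ROI '", roi$name,
         "' maps outside the grid (voxel ", paste(anchor, collapse = ","), ")")
  ex <- roi$extent_px
  xs <- sort(anchor[1] + roi$x_dir * (0:(ex[1] - 1L)))
  ys <- anchor[2] + 0:(ex[2] - 1L)
  zs <- anchor[3] + 0:(ex[3] - 1L)
  vox <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  if (any(vox < 0L) || any(t(vox) >= grid_shape))
    stop("roi_to_voxels: ROI '", roi$name, "' block extends outside the grid")
  storage.mode(vox) <- "integer"
  vox
}

## linear (1-based) indices into a 3D grid for a 0-based voxel matrix
voxel_linear_index <- function(vox, grid_shape) {
  1L + vox[, 1] + grid_shape[1] * (vox[, 2] + grid_shape[2] * vox[, 3])
}

#' Write a BOLD run to a NIfTI-1 file
#'
#' Voxel sizes go to `pixdim[1:3]`, the repetition time to the time-axis
#' spacing `pixdim[4]`, and the origin to the qform translation.
#'
#' @param run a [bold_run()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxel_size_mm, run$tr_s)
  xfm <- diag(c(run$voxel_size_mm, 1))
  xfm[1:3, 4] <- run$origin_mm
  RNifti::qform(img) <- structure(xfm, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a BOLD run from a NIfTI-1 file
#'
#' @param path NIfTI file containing a 4D time series.
#' @param n_dummy number of leading dummy volumes in the file (NIfTI has no
#'   standard slot for this; it normally comes from the session manifest).
#' @param rat_id,condition labels to attach.
#' @param scale_voxels multiply header voxel sizes on read (the rodent
#'   convention of presenting a small brain to human-template tooling at
#'   10x scale). Affects geometry only; correlation statistics are
#'   unchanged. Default 1 (off).
#' @return A [bold_run()].
#' @export
read_run <- function(path, n_dummy = 0L, rat_id = NA_character_,
                     condition = NA_character_, scale_voxels = 1) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 3L)
    stop("read_run: '", path, "' is a 3D volume; a 4D (x, y, z, t) time ",
         "series is required")
  if (length(d) != 4L)
    stop("read_run: '", path, "' has ", length(d), " dimensions; 4 required")
  pd <- RNifti::pixdim(img)
  if (length(pd) < 4L || !is.finite(pd[4]) || pd[4] <= 0)
    stop("read_run: '", path, "' has no usable repetition time in its ",
         "time-axis spacing (pixdim[4])")
  xfm <- RNifti::xform(img)
  origin <- xfm[1:3, 4]
  arr <- array(as.vector(img), dim = d)  # strip NIfTI attributes
  bold_run(data = arr,
           voxel_size_mm = pd[1:3] * scale_voxels,
           origin_mm = origin * scale_voxels,
           tr_s = pd[4], n_dummy = n_dummy,
           rat_id = rat_id, condition = condition)
}

#' Read a session manifest written by [simulate_cohort()]
#'
#' @param path CSV with columns `rat_id, condition, path, is_outlier`.
#' @param base_dir directory against which relative run paths are resolved;
#'   defaults to the manifest's own directory.
#' @return data.frame with absolute paths.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("rat_id", "condition", "path", "is_outlier")
  if (!all(need %in% names(m)))
    stop("read_manifest: missing columns: ",
         paste(setdiff(need, names(m)), collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(base_dir, m$path[rel])
  m
}
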