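# Core data model: 3D ultrasound volumes, ROI geometry, quantization.
#
# Axis convention (fixed): array dim 1 = z (depth below the probe face),
# dim 2 = x (transducer width), dim 3 = y (mechanical sweep). The coronal
# plane -- the plane parallel to the skin, unique to automated 3D ultrasound
# -- is x-y at fixed z. Voxel i along an axis with spacing s covers the
# half-open physical interval [i*s, (i+1)*s) mm, so its center sits at
# (i + 0.5)*s. Indices are 0-based throughout the geometry API.

#' Construct an ultrasound volume
#'
#' Bundles a 3D intensity array with per-axis voxel spacing and the fixed
#' axis semantics (depth, width, sweep).
#'
#' @param data 3D numeric array of nonnegative, finite intensities with
#'   dims ordered (depth z, width x, sweep y); at least 2 samples per axis.
#' @param spacing numeric length-3 vector of voxel sizes in mm, ordered
#'   (depth, width, sweep); all strictly positive.
#' @return An object of class `us_volume`: a list with elements `data`,
#'   `spacing` (named `z`, `x`, `y`) and `axes` (always `"zxy"`).
#' @examples
#' v <- ultrasound_volume(array(runif(8 * 8 * 8), c(8, 8, 8)),
#'                        spacing = c(0.07, 0.07, 0.53))
#' volume_extent_mm(v)
#' @export
ultrasound_volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (depth, width, sweep)", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 samples per axis", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume intensities must be finite", call. = FALSE)
  if (any(data < 0))
    stop("volume intensities must be nonnegative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm (depth, width, sweep)",
         call. = FALSE)
  names(spacing) <- c("z", "x", "y")
  structure(list(data = data, spacing = spacing, axes = "zxy"),
            class = "us_volume")
}

#' @export
print.us_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<us_volume> %d x %d x %d voxels (z depth, x width, y sweep)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing  %.4g x %.4g x %.4g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  extent   %.3g x %.3g x %.3g mm\n",
              d[1] * x$spacing[1], d[2] * x$spacing[2], d[3] * x$spacing[3]))
  invisible(x)
}

#' Physical extent of a volume
#'
#' @param volume a `us_volume`.
#' @return numeric length-3: extent in mm along (depth, width, sweep).
#' @export
volume_extent_mm <- function(volume) {
  stopifnot(inherits(volume, "us_volume"))
  dim(volume$data) * volume$spacing
}

# round-half-up; base round() is half-even and would give 18 for 18.5
round_half_up <- function(x) floor(x + 0.5)

#' Extract a region of interest from a volume
#'
#' Converts a physical box (center + size in mm) to voxel indices. Voxel
#' counts are round-half-up of `size_mm / spacing`, which reproduces the
#' canonical 143 x 143 x 19 voxel ROI for a 10 mm cube at 0.07 mm in-plane
#' and 0.53 mm sweep spacing. The origin is chosen so the ROI center voxel
#' is nearest to `center_mm`. A box that does not fit inside the volume is
#' an error -- never silently clipped.
#'
#' @param volume a `us_volume`.
#' @param center_mm physical center, mm triple ordered (depth, width, sweep).
#' @param size_mm physical box size, mm triple; default `c(10, 10, 10)`.
#' @return An object of class `roi3d`: list with 0-based `origin`, `size`
#'   (voxels), `spacing`, `physical_size` (mm) and the cropped intensity
#'   array `data`.
#' @export
extract_roi <- function(volume, center_mm, size_mm = c(10, 10, 10)) {
  stopifnot(inherits(volume, "us_volume"))
  center_mm <- as.numeric(center_mm)
  size_mm <- as.numeric(size_mm)
  if (length(center_mm) != 3L || length(size_mm) != 3L ||
      !all(is.finite(c(center_mm, size_mm))) || any(size_mm <= 0))
    stop("`center_mm` and `size_mm` must be finite mm triples, size > 0",
         call. = FALSE)
  sp <- volume$spacing
  size_vox <- pmax(1L, as.integer(round_half_up(size_mm / sp)))
  # ideal 0-based origin in continuous voxel coordinates
  origin <- as.integer(round_half_up(center_mm / sp - size_vox / 2))
  d <- dim(volume$data)
  if (any(origin < 0L) || any(origin + size_vox > d))
    stop(sprintf(
      "ROI [%s]+[%s] voxels exceeds volume bounds [%s]",
      paste(origin, collapse = ","), paste(size_vox, collapse = ","),
      paste(d, collapse = ",")), call. = FALSE)
  idx <- Map(function(o, s) seq.int(o + 1L, o + s), origin, size_vox)
  structure(list(
    origin = origin,
    size = size_vox,
    spacing = sp,
    physical_size = size_vox * sp,
    data = volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  ), class = "roi3d")
}

#' @export
print.roi3d <- function(x, ...) {
  cat(sprintf("<roi3d> origin (%s), size (%s) voxels = %.3g x %.3g x %.3g mm\n",
              paste(x$origin, collapse = ","), paste(x$size, collapse = ","),
              x$physical_size[1], x$physical_size[2], x$physical_size[3]))
  invisible(x)
}

#' Extract a 2D slice from a 3D ROI
#'
#' `coronal` is the width x sweep lattice at fixed depth (the plane parallel
#' to the skin where mesh pore texture is visible); `axial` is width x depth
#' at fixed sweep (the conventional B-mode frame); `sagittal` is depth x
#' sweep at fixed width.
#'
#' @param roi a `roi3d`.
#' @param plane one of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param index 0-based slice index within the fixed axis; default the
#'   central slice `floor((n - 1) / 2)`.
#' @return An object of class `roi2d`: list with `data` (matrix), `spacing`
#'   (mm per axis of the matrix), `plane` and `index`.
#' @export
slice_plane <- function(roi, plane = c("coronal", "axial", "sagittal"),
                        index = NULL) {
  stopifnot(inherits(roi, "roi3d"))
  plane <- match.arg(plane)
  fixed_axis <- switch(plane, coronal = 1L, sagittal = 2L, axial = 3L)
  n <- roi$size[fixed_axis]
  if (is.null(index)) index <- (n - 1L) %/% 2L
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 0L || index >= n)
    stop(sprintf("slice index %d out of range [0, %d) for %s plane",
                 index, n, plane), call. = FALSE)
  i <- index + 1L
  sp <- roi$spacing
  sl <- switch(plane,
    coronal  = list(data = roi$data[i, , ], spacing = sp[c("x", "y")]),
    axial    = list(data = roi$data[, , i], spacing = sp[c("z", "x")]),
    sagittal = list(data = roi$data[, i, ], spacing = sp[c("z", "y")]))
  structure(list(data = as.matrix(sl$data), spacing = sl$spacing,
                 plane = plane, index = index),
            class = "roi2d")
}

#' @export
print.roi2d <- function(x, ...) {
  cat(sprintf("<roi2d> %s slice %d: %d x %d pixels at %.4g x %.4g mm\n",
              x$plane, x$index, nrow(x$data), ncol(x$data),
              x$spacing[1], x$spacing[2]))
  invisible(x)
}

#' Quantize a region to G gray levels
#'
#' Uniform min-max binning of the region's own intensity range into `G`
#' levels `0 .. G-1`. A constant region maps entirely to level 0 so that
#' degenerate inputs flow into the co-occurrence code (which has its own
#' documented degenerate-case behavior). Quantization is per region, not
#' global; see the methods vignette for the rationale.
#'
#' @param region a `roi2d`, `roi3d`, or bare numeric matrix/array.
#' @param G number of gray levels, integer >= 2 (default 32).
#' @return A `quantized_region`: integer array of the same shape with
#'   values in `[0, G-1]` and attribute `G`.
#' @export
quantize <- function(region, G = 32L) {
  G <- as.integer(G)
  if (is.na(G) || G < 2L)
    stop("`G` must be an integer >= 2", call. = FALSE)
  x <- if (inherits(region, c("roi2d", "roi3d"))) region$data else region
  if (!is.numeric(x)) stop("region must be numeric", call. = FALSE)
  rng <- range(x)
  if (rng[2] > rng[1]) {
    lev <- floor((x - rng[1]) / (rng[2] - rng[1]) * G)
    lev[lev > G - 1L] <- G - 1L   # x == max lands in the top bin
  } else {
    lev <- array(0L, dim = if (is.null(dim(x))) length(x) else dim(x))
  }
  storage.mode(lev) <- "integer"
  structure(lev, G = G, class = "quantized_region")
}

#' @export
print.quantized_region <- function(x, ...) {
  cat(sprintf("<quantized_region> %s, G = %d levels\n",
              paste(dim(x), collapse = " x "), attr(x, "G")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 I/O. The format is a fixed 348-byte header followed by the
# raw array; only single-frame grayscale volumes are handled. .gz handled
# transparently via gzfile().

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1
#'
#' Float32 single-file NIfTI-1 (`.nii` or `.nii.gz`). Array axes are stored
#' in the package's (depth, width, sweep) order with spacing in `pixdim`.
#'
#' @param volume a `us_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "us_volume"))
  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  d <- dim(volume$data)
  writeBin(348L, con, size = 4)                               # sizeof_hdr
  writeBin(raw(36), con)                                      # unused
  writeBin(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), con, size = 2)  # dim[8]
  writeBin(raw(14), con)                                      # intent etc.
  writeBin(c(16L, 32L), con, size = 2)                        # float32
  writeBin(0L, con, size = 2)                                 # slice_start
  writeBin(c(1, volume$spacing, 0, 0, 0, 0), con, size = 4)   # pixdim[8]
  writeBin(352, con, size = 4)                                # vox_offset
  writeBin(c(1, 0), con, size = 4)                            # scl slope/inter
  writeBin(raw(2 + 1 + 1), con)                               # slice_end..
  writeBin(c(0, 0), con, size = 4)                            # cal_max/min
  writeBin(c(0, 0), con, size = 4)                            # slice_dur, toffset
  writeBin(c(0L, 0L), con, size = 4)                          # glmax/glmin
  desc <- charToRaw("poretex us_volume zxy")
  writeBin(c(desc, raw(80 - length(desc))), con)              # descrip
  writeBin(raw(24), con)                                      # aux_file
  writeBin(c(0L, 0L), con, size = 2)                          # qform, sform
  writeBin(numeric(18), con, size = 4)                        # quatern/srow
  writeBin(raw(16), con)                                      # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)               # magic
  writeBin(raw(4), con)                                       # extension flag
  writeBin(as.numeric(volume$data), con, size = 4)
  invisible(path)
}

.nifti_dtype <- function(code) {
  switch(as.character(code),
    "2"   = list(what = "integer", size = 1, signed = FALSE),
    "4"   = list(what = "integer", size = 2, signed = TRUE),
    "8"   = list(what = "integer", size = 4, signed = TRUE),
    "16"  = list(what = "numeric", size = 4, signed = TRUE),
    "64"  = list(what = "numeric", size = 8, signed = TRUE),
    "512" = list(what = "integer", size = 2, signed = FALSE),
    stop(sprintf("unsupported NIfTI datatype code %s", code), call. = FALSE))
}

#' Load a 3D ultrasound volume
#'
#' Reads a single-file NIfTI-1 volume (`.nii`, optionally gzipped). Spacing
#' is taken from the header `pixdim`; a JSON sidecar
#' `{"spacing_mm": [z, x, y], "axes": "zxy"}` overrides it for containers
#' written without physical metadata. Missing or zero spacing from both
#' sources is a configuration error; multi-frame (4D) input is rejected as
#' non-grayscale.
#'
#' @param path NIfTI file path.
#' @param sidecar optional path to a JSON metadata sidecar.
#' @return a `us_volume`.
#' @export
load_volume <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (hdr_size != 348L) {
    endian <- "big"
    if (.swap_int32(hdr_size) != 348L)
      stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  readBin(con, "raw", 36)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  ndim <- dims[1]
  if (ndim > 3L && any(dims[5:8] > 1L))
    stop("non-grayscale / multi-frame NIfTI not supported: ", path,
         call. = FALSE)
  if (ndim < 3L) stop("expected a 3D volume: ", path, call. = FALSE)
  d <- dims[2:4]
  readBin(con, "raw", 14)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)        # bitpix
  readBin(con, "integer", 1, size = 2, endian = endian)        # slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  readBin(con, "raw", 352 - 120)                  # rest of header + ext flag
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", skip)
  dt <- .nifti_dtype(datatype)
  x <- readBin(con, dt$what, prod(d), size = dt$size, signed = dt$signed,
               endian = endian)
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0))
    x <- x * slope + inter
  spacing <- pixdim[2:4]
  axes <- "zxy"
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$spacing_mm)) spacing <- as.numeric(meta$spacing_mm)
    if (!is.null(meta$axes)) axes <- meta$axes
  }
  if (!all(is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing missing or nonpositive; supply a sidecar with ",
         "spacing_mm", call. = FALSE)
  arr <- array(x, dim = d)
  if (!identical(axes, "zxy")) {
    perm <- match(c("z", "x", "y"), strsplit(axes, "")[[1]])
    if (any(is.na(perm)))
      stop("sidecar axes must be a permutation of \"zxy\"", call. = FALSE)
    arr <- aperm(arr, perm)
    spacing <- spacing[perm]
  }
  ultrasound_volume(arr, spacing)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(rev(b), "integer", 1, size = 4, endian = "little")
}
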