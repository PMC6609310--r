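#' Read a NIfTI-1 image as a Volume4D
#'
#' 3D images are promoted to a single-volume 4D grid. Voxel sizes and TR are
#' taken from the header pixdim, the affine from the sform/qform.
#'
#' @param path path to a .nii or .nii.gz file
#' @return a [Volume4D-class] object
#' @export
readVolume4D <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read NIfTI file '%s': no such file", path),
         call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI file '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))   # plain numeric array
  nd <- length(dim(a))
  if (nd < 3L || nd > 4L)
    stop(sprintf("'%s' has %d dimensions; expected a 3D or 4D image",
                 path, nd), call. = FALSE)
  if (nd == 3L) dim(a) <- c(dim(a), 1L)
  hdr <- RNifti::niftiHeader(img)
  vox <- abs(hdr$pixdim[2:4])
  vox[vox == 0] <- 1
  tr <- if (nd == 4L) abs(hdr$pixdim[5]) else 0
  aff <- structure(unclass(RNifti::xform(img))[1:4, 1:4], dimnames = NULL)
  new("Volume4D", data = a, voxelSize = vox, affine = aff, tr = tr)
}

#' Write a Volume4D (or Mask3D) to a NIfTI-1 file
#'
#' Data are stored as float64 so that write/read round-trips are exact;
#' single-volume images are written as 3D. Masks are written as 0/1.
#'
#' @param vol a [Volume4D-class] or [Mask3D-class]
#' @param path output path (.nii or .nii.gz)
#' @return `path`, invisibly
#' @export
writeVolume4D <- function(vol, path) {
  if (is(vol, "Mask3D")) {
    a <- array(as.double(vol@data), dim = dim(vol@data))
    vox <- sqrt(colSums(vol@affine[1:3, 1:3]^2))
    tr <- 0
    aff <- vol@affine
  } else {
    stopifnot(is(vol, "Volume4D"))
    a <- vol@data
    if (dim(a)[4L] == 1L) dim(a) <- dim(a)[1:3]
    vox <- vol@voxelSize
    tr <- vol@tr
    aff <- vol@affine
  }
  im <- RNifti::asNifti(a, datatype = "float64")
  im <- RNifti::asNifti(im,
    reference = list(pixdim = c(0, vox, tr, 0, 0, 0)))
  RNifti::sform(im) <- structure(aff, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Gray-matter mask from a tissue-density map
#'
#' A voxel enters the mask iff its gray-matter density strictly exceeds the
#' threshold (default 0.2, i.e. 20\% gray-matter density).
#'
#' @param density a [Volume4D-class] with a single volume, values in [0, 1]
#' @param threshold density threshold in (0, 1)
#' @return a [Mask3D-class]
#' @export
buildGrayMatterMask <- function(density, threshold = 0.2) {
  stopifnot(is(density, "Volume4D"))
  if (dim(density)[4L] != 1L)
    stop("density map must have a single volume", call. = FALSE)
  d <- density@data[, , , 1L, drop = FALSE]
  dim(d) <- dim(density@data)[1:3]
  if (anyNA(d) || min(d) < 0 || max(d) > 1)
    stop("density values must lie in [0, 1]", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  new("Mask3D", data = d > threshold, affine = density@affine)
}

#' Functional brain mask from temporal minima
#'
#' Computes each voxel's minimum over time and keeps voxels whose minimum
#' strictly exceeds the given percentile (linear-interpolation definition,
#' over all in-grid voxels) of the minima map. With a low percentile this
#' retains voxels that never drop to background intensity.
#'
#' @param vol a [Volume4D-class]
#' @param percentile percentile in (0, 100); default 20
#' @return a [Mask3D-class]
#' @export
buildFunctionalMask <- function(vol, percentile = 20) {
  stopifnot(is(vol, "Volume4D"))
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)", call. = FALSE)
  d <- dim(vol)[1:3]
  mins <- apply(vol@data, c(1L, 2L, 3L), min)
  thr <- quantile(as.vector(mins), probs = percentile / 100,
                  names = FALSE, type = 7)
  new("Mask3D", data = array(mins > thr, dim = d), affine = vol@affine)
}

#' Combine per-subject masks into a group mask
#'
#' A voxel enters the group mask iff the mean of the subject masks at that
#' voxel is at least `fraction` (inclusive, so 3 of 4 subjects passes the
#' default 0.75).
#'
#' @param masks list of [Mask3D-class] on identical grids
#' @param fraction required fraction of subjects, in (0, 1]
#' @return a [Mask3D-class]
#' @export
combineGroupMasks <- function(masks, fraction = 0.75) {
  stopifnot(length(masks) >= 1L, fraction > 0, fraction <= 1)
  ref <- masks[[1L]]
  acc <- array(0, dim = dim(ref))
  for (m in masks) {
    if (!same_grid(dim(ref), ref@affine, dim(m), m@affine))
      stop_shape("masks are on different grids")
    acc <- acc + m@data
  }
  new("Mask3D", data = acc / length(masks) >= fraction, affine = ref@affine)
}

#' Intersect masks, with optional exclusions
#'
#' Voxelwise AND over `masks`, then AND NOT over `exclusions` (e.g. a
#' cerebellum mask supplied by the user).
#'
#' @param masks list of [Mask3D-class] to intersect
#' @param exclusions optional list of [Mask3D-class] to subtract
#' @return a [Mask3D-class]
#' @export
intersectMasks <- function(masks, exclusions = list()) {
  stopifnot(length(masks) >= 1L)
  ref <- masks[[1L]]
  acc <- array(TRUE, dim = dim(ref))
  for (m in masks) {
    if (!same_grid(dim(ref), ref@affine, dim(m), m@affine))
      stop_shape("masks are on different grids")
    acc <- acc & m@data
  }
  for (m in exclusions) {
    if (!same_grid(dim(ref), ref@affine, dim(m), m@affine))
      stop_shape("exclusion mask is on a different grid")
    acc <- acc & !m@data
  }
  new("Mask3D", data = acc, affine = ref@affine)
}

#' Extract in-mask voxel time series as an N x T matrix
#'
#' Rows follow column-major grid traversal (x fastest, then y, then z), the
#' fixed convention used throughout the package, so [insertMap()] is an exact
#' inverse on in-mask voxels.
#'
#' @param vol a [Volume4D-class]
#' @param mask a [Mask3D-class] on the same grid
#' @return a [TimeSeriesMatrix-class]
#' @export
extractTimeseries <- function(vol, mask) {
  stopifnot(is(vol, "Volume4D"), is(mask, "Mask3D"))
  if (!same_grid(dim(vol)[1:3], vol@affine, dim(mask), mask@affine))
    stop_shape("volume and mask are on different grids")
  n <- sum(mask@data)
  if (n < 1L) stop("mask is empty", call. = FALSE)
  d <- dim(vol)
  idx <- which(mask@data)                  # column-major: x fastest
  mat <- matrix(vol@data, nrow = prod(d[1:3]), ncol = d[4L])[idx, , drop = FALSE]
  new("TimeSeriesMatrix", values = mat,
      voxelIndex = arrayInd(idx, d[1:3]),
      gridDim = as.integer(d[1:3]), tr = vol@tr)
}

#' Place masked values back onto the image grid
#'
#' The inverse of [extractTimeseries()]: a length-N vector becomes one
#' volume, an N x M matrix becomes M volumes; out-of-mask voxels are set to
#' `fill`.
#'
#' @param values length-N vector or N x M matrix, rows in mask traversal order
#' @param mask a [Mask3D-class] with N in-mask voxels
#' @param fill value for out-of-mask voxels (default 0)
#' @param tr repetition time stored in the result (default 0)
#' @return a [Volume4D-class] with M volumes
#' @export
insertMap <- function(values, mask, fill = 0, tr = 0) {
  stopifnot(is(mask, "Mask3D"))
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  n <- sum(mask@data)
  if (nrow(values) != n)
    stop_shape("value rows (%d) do not match mask count (%d)",
               nrow(values), n)
  d <- dim(mask)
  out <- matrix(fill, nrow = prod(d), ncol = ncol(values))
  out[which(mask@data), ] <- values
  vox <- sqrt(colSums(mask@affine[1:3, 1:3]^2))
  new("Volume4D", data = array(out, dim = c(d, ncol(values))),
      voxelSize = vox, affine = mask@affine, tr = tr)
}

#' Construct a Mask3D from a thresholded image file or array
#'
#' Convenience constructor: nonzero voxels of a 3D image become the mask.
#'
#' @param x a [Volume4D-class] with one volume, or a 3D array
#' @param affine affine to attach when `x` is a bare array
#' @return a [Mask3D-class]
#' @export
asMask3D <- function(x, affine = diag(4)) {
  if (is(x, "Volume4D")) {
    if (dim(x)[4L] != 1L) stop("expected a single-volume image", call. = FALSE)
    d <- x@data[, , , 1L, drop = FALSE] != 0
    dim(d) <- dim(x@data)[1:3]
    new("Mask3D", data = d, affine = x@affine)
  } else {
    stopifnot(length(dim(x)) == 3L)
    new("Mask3D", data = x != 0, affine = affine)
  }
}
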