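#' Build a TemplateSet from masked template maps
#'
#' @param maps numeric N x K matrix of spatial Z-maps sampled at the in-mask
#'   voxels (rows in mask traversal order)
#' @param names K network labels (default "network1"...)
#' @param zthreshold Z threshold used to derive per-network test masks
#'   (default 3.0)
#' @return a [TemplateSet-class]
#' @export
templateSet <- function(maps, names = NULL, zthreshold = 3.0) {
  maps <- as.matrix(maps)
  if (is.null(names)) names <- paste0("network", seq_len(ncol(maps)))
  new("TemplateSet", maps = maps, names = as.character(names),
      zthreshold = zthreshold)
}

#' Read a TemplateSet from a 4D NIfTI file
#'
#' One network Z-map per volume, sampled at the in-mask voxels.
#'
#' @param path 4D NIfTI file, one network per volume
#' @param mask analysis [Mask3D-class]
#' @param names optional labels, or a file with one label per line
#' @param zthreshold see [templateSet()]
#' @return a [TemplateSet-class]
#' @export
readTemplateSet <- function(path, mask, names = NULL, zthreshold = 3.0) {
  vol <- readVolume4D(path)
  ts <- extractTimeseries(vol, mask)
  if (is.character(names) && length(names) == 1L && file.exists(names))
    names <- readLines(names)
  templateSet(ts@values, names = names, zthreshold = zthreshold)
}

# checked joint OLS solve; names offending pair on collinearity
.solve_design <- function(x, what) {
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- sort(qrx$pivot[(qrx$rank + 1L):ncol(x)])
    stop(sprintf("degenerate %s design: column(s) %s collinear with the rest",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  qrx
}

#' Stage 1 of dual regression: spatial regression
#'
#' Regresses every window's centrality map jointly onto all K spatially
#' demeaned templates (multiple regression), yielding one time course per
#' network per subject. Map columns are spatially demeaned as well, the
#' standard dual-regression convention.
#'
#' @param cs a [CentralitySeries-class] or N x M matrix
#' @param templates a [TemplateSet-class] on the same voxel set
#' @return a [SubjectTimecourses-class] (K x M)
#' @export
stage1SpatialRegression <- function(cs, templates) {
  y <- if (is(cs, "CentralitySeries")) cs@values else as.matrix(cs)
  stopifnot(is(templates, "TemplateSet"))
  c0 <- templates@maps
  if (nrow(y) != nrow(c0))
    stop_shape("maps have %d voxels but templates have %d",
               nrow(y), nrow(c0))
  if (ncol(c0) >= nrow(c0))
    stop("more templates than voxels", call. = FALSE)
  cd <- sweep(c0, 2L, colMeans(c0))
  yd <- sweep(y, 2L, colMeans(y))
  qrc <- .solve_design(cd, "template")
  s <- qr.coef(qrc, yd)                       # K x M
  new("SubjectTimecourses", values = unname(s),
      varianceNormalized = FALSE, names = templates@names)
}

#' Variance-normalize stage-1 time courses
#'
#' Scales each network's time course to unit sample standard deviation so
#' that stage-2 coefficients are comparable across subjects.
#'
#' @param s a [SubjectTimecourses-class]
#' @return a [SubjectTimecourses-class] with unit-SD rows
#' @export
normalizeTimecourses <- function(s) {
  stopifnot(is(s, "SubjectTimecourses"))
  sds <- apply(s@values, 1L, sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance time course for network '%s'",
                 s@names[which(sds == 0)[1L]]), call. = FALSE)
  new("SubjectTimecourses", values = s@values / sds,
      varianceNormalized = TRUE, names = s@names)
}

#' Stage 2 of dual regression: temporal regression
#'
#' Regresses each voxel's centrality time course on all K network time
#' courses plus an intercept; the coefficients form the K voxelwise
#' correspondence maps for the subject.
#'
#' @param cs a [CentralitySeries-class] or N x M matrix
#' @param s a [SubjectTimecourses-class] (K x M)
#' @return a [SubjectSpatialMaps-class] (N x K)
#' @export
stage2TemporalRegression <- function(cs, s) {
  y <- if (is(cs, "CentralitySeries")) cs@values else as.matrix(cs)
  stopifnot(is(s, "SubjectTimecourses"))
  if (ncol(y) != ncol(s@values))
    stop_shape("maps have %d windows but time courses have %d",
               ncol(y), ncol(s@values))
  x <- cbind(1, t(s@values))                  # M x (K+1)
  qrx <- .solve_design(x, "time-course")
  b <- qr.coef(qrx, t(y))                     # (K+1) x N
  new("SubjectSpatialMaps", values = t(b[-1L, , drop = FALSE]),
      names = s@names)
}

#' Per-network test mask from a template Z-map
#'
#' Voxels where the template's Z strictly exceeds the set's Z threshold,
#' intersected with the analysis mask; group statistics are evaluated only
#' inside this mask.
#'
#' @param templates a [TemplateSet-class]
#' @param k network index
#' @param mask analysis [Mask3D-class] whose count equals the template rows
#' @return a [Mask3D-class] (possibly empty, with a warning)
#' @export
makeNetworkMask <- function(templates, k, mask) {
  stopifnot(is(templates, "TemplateSet"), is(mask, "Mask3D"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(templates@maps))
    stop("network index out of range", call. = FALSE)
  if (nrow(templates@maps) != sum(mask@data))
    stop_shape("template rows (%d) do not match mask count (%d)",
               nrow(templates@maps), sum(mask@data))
  sel <- templates@maps[, k] > templates@zthreshold
  d <- array(FALSE, dim = dim(mask))
  d[which(mask@data)[sel]] <- TRUE
  if (!any(d))
    warning(sprintf("network mask for '%s' is empty at Z > %g",
                    templates@names[k], templates@zthreshold))
  new("Mask3D", data = d, affine = mask@affine)
}
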