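#' Accessors for decm classes
#'
#' Small read-only accessors for the package's S4 carriers. Slot access via
#' `@` is internal; user code should go through these.
#'
#' @param x an object of the documented class
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("affineMat", function(x) standardGeneric("affineMat"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("maskCount", function(x) standardGeneric("maskCount"))
#' @rdname accessors
#' @export
setGeneric("voxelIndex", function(x) standardGeneric("voxelIndex"))
#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))
#' @rdname accessors
#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))
#' @rdname accessors
#' @export
setGeneric("networkNames", function(x) standardGeneric("networkNames"))
#' @rdname accessors
#' @export
setGeneric("degenerateRows", function(x) standardGeneric("degenerateRows"))

setMethod("imgData", "Volume4D", function(x) x@data)
setMethod("voxelSize", "Volume4D", function(x) x@voxelSize)
setMethod("affineMat", "Volume4D", function(x) x@affine)
setMethod("repetitionTime", "Volume4D", function(x) x@tr)
setMethod("repetitionTime", "TimeSeriesMatrix", function(x) x@tr)
setMethod("repetitionTime", "CentralitySeries", function(x) x@tr)
setMethod("imgData", "Mask3D", function(x) x@data)
setMethod("affineMat", "Mask3D", function(x) x@affine)
setMethod("maskCount", "Mask3D", function(x) sum(x@data))
setMethod("voxelIndex", "TimeSeriesMatrix", function(x) x@voxelIndex)
setMethod("seriesValues", "TimeSeriesMatrix", function(x) x@values)
setMethod("seriesValues", "CentralitySeries", function(x) x@values)
setMethod("seriesValues", "SubjectTimecourses", function(x) x@values)
setMethod("seriesValues", "SubjectSpatialMaps", function(x) x@values)
setMethod("seriesValues", "TemplateSet", function(x) x@maps)
setMethod("windowLength", "CentralitySeries", function(x) x@windowLength)
setMethod("networkNames", "TemplateSet", function(x) x@names)
setMethod("networkNames", "SubjectTimecourses", function(x) x@names)
setMethod("networkNames", "SubjectSpatialMaps", function(x) x@names)
setMethod("degenerateRows", "NormalizedSeries", function(x) x@degenerateRows)

#' @rdname accessors
#' @export
setMethod("dim", "Volume4D", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("dim", "Mask3D", function(x) dim(x@data))

setMethod("show", "Volume4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume4D: %d x %d x %d grid, %d volume(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxels %.4g x %.4g x %.4g mm, TR %.4g s\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              object@tr))
})

setMethod("show", "Mask3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Mask3D: %d x %d x %d grid, %d in-mask voxel(s)\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "TimeSeriesMatrix", function(object) {
  cat(sprintf("TimeSeriesMatrix: %d voxels x %d time points (TR %.4g s)\n",
              nrow(object@values), ncol(object@values), object@tr))
})

setMethod("show", "CentralitySeries", function(object) {
  cat(sprintf(
    "CentralitySeries: %d voxels x %d windows (window length %d, TR %.4g s)\n",
    nrow(object@values), ncol(object@values), object@windowLength, object@tr))
  cat(sprintf("  converged windows: %d/%d; scaling target mean %.6g\n",
              sum(object@converged), length(object@converged),
              object@targetMean))
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: %d voxels x %d networks (Z threshold %.3g)\n",
              nrow(object@maps), ncol(object@maps), object@zthreshold))
  cat("  ", paste(object@names, collapse = ", "), "\n")
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: %d voxels, %d permutations (seed %d%s)\n",
    length(object@tmap), object@nPerm, object@seed,
    if (object@exhaustive) ", exhaustive" else ""))
  cat(sprintf("  min corrected p: %.4g\n", min(object@pcorr)))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %dx%dx%d grid, T=%d, %d networks, %d+%d subjects\n",
    object@grid[1], object@grid[2], object@grid[3], object@nTime,
    object@nNetworks, object@nPerGroup, object@nPerGroup))
  cat(sprintf("  coupling mean %.3g, drift SD %.3g/%.3g, effect network %d\n",
              object@couplingMean, object@couplingSd[1], object@couplingSd[2],
              object@effectNetwork))
})
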