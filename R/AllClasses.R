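#' @import methods
#' @importFrom stats quantile sd cor rnorm runif median setNames
#' @importFrom utils head read.table write.table combn
#' @useDynLib decm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Central data carriers. All voxelwise matrices share one convention:
## rows are in-mask voxels in column-major grid traversal (x fastest, then
## y, then z), so that maps reconstructed from them are byte-reproducible.

#' Volume4D: a 4D image grid
#'
#' Carrier for raw fMRI series and centrality map series: an X-by-Y-by-Z-by-T
#' array with voxel dimensions (mm), a 4x4 voxel-to-world affine and the
#' repetition time (seconds). 3D images are represented with T = 1.
#'
#' @slot data four-dimensional numeric array
#' @slot voxelSize numeric length-3, voxel edge lengths in mm (positive)
#' @slot affine 4x4 voxel-to-world matrix (invertible)
#' @slot tr repetition time in seconds (0 when undefined, e.g. for masks)
#' @exportClass Volume4D
setClass("Volume4D",
  representation(data = "array", voxelSize = "numeric",
                 affine = "matrix", tr = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("data must be a 4D array")
    if (any(d < 1L)) return("all dimensions must be >= 1")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be 3 strictly positive values")
    if (!all(dim(object@affine) == c(4L, 4L)))
      return("affine must be a 4x4 matrix")
    if (abs(det(object@affine)) < .Machine$double.eps)
      return("affine must be invertible")
    if (length(object@tr) != 1L || object@tr < 0)
      return("tr must be a single nonnegative number")
    TRUE
  })

#' Mask3D: a binary 3D voxel mask
#'
#' @slot data logical X-by-Y-by-Z array
#' @slot affine 4x4 voxel-to-world matrix of the grid the mask lives on
#' @exportClass Mask3D
setClass("Mask3D",
  representation(data = "array", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (!is.logical(object@data)) return("mask data must be logical")
    if (anyNA(object@data)) return("mask must not contain NA")
    if (!all(dim(object@affine) == c(4L, 4L)))
      return("affine must be a 4x4 matrix")
    TRUE
  })

#' TimeSeriesMatrix: masked voxel-by-time data
#'
#' N in-mask voxel time series of length T, with the voxel-to-grid index map
#' that makes extraction invertible.
#'
#' @slot values N-by-T numeric matrix
#' @slot voxelIndex N-by-3 integer matrix of (x,y,z) grid coordinates,
#'   in column-major traversal order of the originating mask
#' @slot gridDim length-3 integer grid shape
#' @slot tr repetition time in seconds
#' @exportClass TimeSeriesMatrix
setClass("TimeSeriesMatrix",
  representation(values = "matrix", voxelIndex = "matrix",
                 gridDim = "integer", tr = "numeric"),
  validity = function(object) {
    if (nrow(object@values) != nrow(object@voxelIndex))
      return("values and voxelIndex row counts differ")
    if (ncol(object@voxelIndex) != 3L)
      return("voxelIndex must have 3 columns")
    if (length(object@gridDim) != 3L) return("gridDim must have length 3")
    lin <- lin_index(object@voxelIndex, object@gridDim)
    if (anyDuplicated(lin)) return("duplicate voxel coordinates")
    if (any(object@voxelIndex < 1L) ||
        any(object@voxelIndex > rep(object@gridDim, each = nrow(object@voxelIndex))))
      return("voxel coordinates outside grid")
    TRUE
  })

#' NormalizedSeries: windowed rows prepared for centrality computation
#'
#' Each non-degenerate row is demeaned and scaled to unit Euclidean norm, so
#' that rows %*% t(rows) is exactly the Pearson correlation matrix of the
#' window. Zero-variance rows are set to zero and recorded.
#'
#' @slot rows N-by-W numeric matrix
#' @slot degenerateRows integer indices of zero-variance rows
#' @exportClass NormalizedSeries
setClass("NormalizedSeries",
  representation(rows = "matrix", degenerateRows = "integer"),
  validity = function(object) {
    if (ncol(object@rows) < 3L) return("window length must be >= 3")
    dg <- object@degenerateRows
    if (length(dg) && (any(dg < 1L) || any(dg > nrow(object@rows))))
      return("degenerateRows out of range")
    TRUE
  })

#' CentralityVector: one eigenvector-centrality map (vector form)
#'
#' @slot values length-N nonnegative centralities, unit Euclidean norm over
#'   non-degenerate entries before any output scaling
#' @slot eigenvalue dominant-eigenvalue estimate of the implicit R+1 matrix
#' @slot iterations number of power iterations performed
#' @slot converged whether the iterate change dropped below tolerance
#' @exportClass CentralityVector
setClass("CentralityVector",
  representation(values = "numeric", eigenvalue = "numeric",
                 iterations = "integer", converged = "logical"),
  validity = function(object) {
    if (any(object@values < 0)) return("centralities must be nonnegative")
    TRUE
  })

#' CentralitySeries: sliding-window centrality time series
#'
#' N voxels by M window positions of scaled eigenvector centralities, plus
#' window metadata. Window length W = T - M + 1; window j covers volumes
#' [j, j + W - 1] (1-based).
#'
#' @slot values N-by-M numeric matrix
#' @slot windowLength window length W in volumes
#' @slot windowStarts integer offsets 0..M-1 (volumes)
#' @slot tr repetition time in seconds
#' @slot iterations per-window power-iteration counts
#' @slot converged per-window convergence flags
#' @slot targetMean the mean-intensity scaling target of each column
#' @exportClass CentralitySeries
setClass("CentralitySeries",
  representation(values = "matrix", windowLength = "integer",
                 windowStarts = "integer", tr = "numeric",
                 iterations = "integer", converged = "logical",
                 targetMean = "numeric"),
  validity = function(object) {
    m <- ncol(object@values)
    if (length(object@windowStarts) != m)
      return("windowStarts length must equal column count")
    if (m > 1L && any(diff(object@windowStarts) != 1L))
      return("windowStarts must increase by 1")
    if (object@windowLength < 3L) return("window length must be >= 3")
    TRUE
  })

#' TemplateSet: spatial network templates on the analysis mask
#'
#' K spatial Z-maps sampled at the N in-mask voxels, used as the design of
#' the spatial (stage-1) dual regression and to derive per-network test masks.
#'
#' @slot maps N-by-K numeric matrix
#' @slot names K network labels
#' @slot zthreshold Z threshold used by [makeNetworkMask()]
#' @exportClass TemplateSet
setClass("TemplateSet",
  representation(maps = "matrix", names = "character", zthreshold = "numeric"),
  validity = function(object) {
    if (ncol(object@maps) < 1L) return("need at least one template")
    if (length(object@names) != ncol(object@maps))
      return("names length must equal template count")
    if (any(colSums(abs(object@maps)) == 0)) return("all-zero template column")
    TRUE
  })

#' SubjectTimecourses: stage-1 dual-regression output
#'
#' @slot values K-by-M matrix of per-network window time courses
#' @slot varianceNormalized whether rows have unit sample SD
#' @slot names K network labels
#' @exportClass SubjectTimecourses
setClass("SubjectTimecourses",
  representation(values = "matrix", varianceNormalized = "logical",
                 names = "character"),
  validity = function(object) {
    if (length(object@names) != nrow(object@values))
      return("names length must equal row count")
    if (isTRUE(object@varianceNormalized)) {
      sds <- apply(object@values, 1L, sd)
      if (any(abs(sds - 1) > 1e-6))
        return("varianceNormalized set but row SDs are not 1")
    }
    TRUE
  })

#' SubjectSpatialMaps: stage-2 dual-regression output
#'
#' @slot values N-by-K matrix of voxelwise correspondence coefficients
#' @slot names K network labels
#' @exportClass SubjectSpatialMaps
setClass("SubjectSpatialMaps",
  representation(values = "matrix", names = "character"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("non-finite coefficients")
    if (length(object@names) != ncol(object@values))
      return("names length must equal column count")
    TRUE
  })

#' GroupDesign: between-subject design for voxelwise contrasts
#'
#' @slot design subjects-by-P design matrix (group indicator, covariates,
#'   intercept), full column rank
#' @slot contrast length-P contrast vector (nonzero)
#' @slot labels subject identifiers
#' @exportClass GroupDesign
setClass("GroupDesign",
  representation(design = "matrix", contrast = "numeric", labels = "character"),
  validity = function(object) {
    p <- ncol(object@design)
    if (length(object@contrast) != p)
      return("contrast length must equal design column count")
    if (all(object@contrast == 0)) return("contrast must be nonzero")
    if (qr(object@design)$rank < p) return("design is rank deficient")
    if (nrow(object@design) < p + 2L)
      return("need at least P + 2 subjects")
    if (length(object@labels) != nrow(object@design))
      return("labels length must equal subject count")
    TRUE
  })

#' TfceParams: threshold-free cluster enhancement parameters
#'
#' Defaults E = 0.5, H = 2 follow the enhancement's standard recommended
#' settings; dh = NA means "max(statistic)/100, per map".
#'
#' @slot eExponent extent exponent E
#' @slot hExponent height exponent H
#' @slot dh integration step (NA for per-map max/100)
#' @slot connectivity 6, 18 or 26 neighbour rule
#' @exportClass TfceParams
setClass("TfceParams",
  representation(eExponent = "numeric", hExponent = "numeric",
                 dh = "numeric", connectivity = "integer"),
  validity = function(object) {
    if (object@eExponent < 0 || object@hExponent < 0)
      return("exponents must be nonnegative")
    if (!is.na(object@dh) && object@dh <= 0) return("dh must be positive")
    if (!object@connectivity %in% c(6L, 18L, 26L))
      return("connectivity must be 6, 18 or 26")
    TRUE
  })

#' PermutationResult: voxelwise permutation inference output
#'
#' @slot tmap observed voxelwise contrast t-statistics (length N)
#' @slot tfceMap TFCE-enhanced observed statistics
#' @slot pcorr FWE-corrected p-values, in [1/(1+nPerm), 1]
#' @slot nullMax per-permutation maximum enhanced statistic
#' @slot nPerm number of permutations
#' @slot seed RNG seed used
#' @slot exhaustive whether all distinct permutations were enumerated
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(tmap = "numeric", tfceMap = "numeric", pcorr = "numeric",
                 nullMax = "numeric", nPerm = "integer", seed = "integer",
                 exhaustive = "logical"),
  validity = function(object) {
    n <- length(object@tmap)
    if (length(object@tfceMap) != n || length(object@pcorr) != n)
      return("tmap, tfceMap and pcorr lengths differ")
    if (length(object@nullMax) != object@nPerm)
      return("nullMax length must equal nPerm")
    lo <- 1 / (1 + object@nPerm)
    if (any(object@pcorr < lo - 1e-12) || any(object@pcorr > 1 + 1e-12))
      return("pcorr outside [1/(1+nPerm), 1]")
    o <- order(object@tfceMap, decreasing = TRUE)
    if (is.unsorted(object@pcorr[o])) return("pcorr not monotone in tfceMap")
    TRUE
  })

#' SynthConfig: synthetic multi-subject cohort configuration
#'
#' Describes the planted structure of a synthetic resting-state cohort:
#' Gaussian-blob network templates, latent network signals with slowly
#' drifting within-network coupling, a between-group difference in coupling
#' variability on one network, white observation noise, and balanced groups.
#'
#' @slot grid X, Y, Z grid shape
#' @slot nTime number of volumes T
#' @slot nNetworks number of planted networks K
#' @slot blobCenters K-by-3 matrix of blob centres (voxel coordinates)
#' @slot blobWidth Gaussian sigma of the blobs, in voxels
#' @slot couplingMean baseline within-network coupling level, in (0,1)
#' @slot couplingSd length-2: temporal coupling-drift SD per group, applied
#'   to the effect network (group A, group B)
#' @slot couplingSdNull coupling-drift SD of non-effect networks (both groups)
#' @slot effectNetwork index of the network carrying the group difference
#'   (0 for a null cohort with no group effect)
#' @slot noiseSd white-noise SD added to every voxel
#' @slot nPerGroup subjects per group
#' @slot tr repetition time in seconds
#' @slot seed master seed; all subject seeds derive from it
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(grid = "integer", nTime = "integer", nNetworks = "integer",
                 blobCenters = "matrix", blobWidth = "numeric",
                 couplingMean = "numeric", couplingSd = "numeric",
                 couplingSdNull = "numeric", effectNetwork = "integer",
                 noiseSd = "numeric", nPerGroup = "integer",
                 tr = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@grid) != 3L || any(object@grid < 4L))
      return("grid must be 3 dimensions, each >= 4")
    if (object@nTime < 5L) return("nTime too small")
    if (object@nNetworks < 1L) return("need at least one network")
    if (nrow(object@blobCenters) != object@nNetworks)
      return("blobCenters must have one row per network")
    if (anyDuplicated(object@blobCenters)) return("blob centres must be distinct")
    if (any(object@blobCenters < 1) ||
        any(t(object@blobCenters) > object@grid))
      return("blob centres outside grid")
    if (object@couplingMean <= 0 || object@couplingMean >= 1)
      return("couplingMean must be in (0,1)")
    if (length(object@couplingSd) != 2L || any(object@couplingSd < 0))
      return("couplingSd must be 2 nonnegative values")
    if (object@effectNetwork < 0L || object@effectNetwork > object@nNetworks)
      return("effectNetwork out of range")
    if (object@nPerGroup < 2L) return("need >= 2 subjects per group")
    TRUE
  })
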