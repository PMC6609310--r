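#' Read a motion-parameter table
#'
#' Whitespace- or tab-delimited text with T rows and P columns (e.g. the six
#' rigid-body realignment parameters). No header is expected; a header line
#' of non-numeric labels is detected and used as column names.
#'
#' @param path path to the text file
#' @return numeric T x P matrix with column names
#' @export
readMotionTable <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read motion file '%s'", path), call. = FALSE)
  first <- scan(path, what = "character", nlines = 1L, quiet = TRUE)
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  tab <- read.table(path, header = has_header)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("motion table is not numeric", call. = FALSE)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("mp", seq_len(ncol(m)))
  m
}

#' Residualize voxel time series against motion confounds
#'
#' Per-voxel ordinary least squares of the time series on an intercept plus
#' the demeaned confound columns; the fitted confound contribution (excluding
#' the intercept) is subtracted. Because the confounds are demeaned before
#' fitting, every voxel's temporal mean is preserved exactly, keeping the
#' data on its original intensity scale; correlation-based centrality is
#' unaffected by the mean.
#'
#' @param y a [TimeSeriesMatrix-class] (N voxels x T)
#' @param confounds numeric T x P matrix of confound regressors
#' @return a [TimeSeriesMatrix-class] of residualized series
#' @export
regressConfounds <- function(y, confounds) {
  stopifnot(is(y, "TimeSeriesMatrix"))
  confounds <- as.matrix(confounds)
  tl <- ncol(y@values)
  p <- ncol(confounds)
  if (nrow(confounds) != tl)
    stop_shape("confound rows (%d) do not match time points (%d)",
               nrow(confounds), tl)
  if (tl <= p + 1L)
    stop(sprintf(
      "insufficient degrees of freedom: T = %d with %d confounds", tl, p),
      call. = FALSE)
  cd <- sweep(confounds, 2L, colMeans(confounds))
  keep <- colSums(cd^2) > 0          # constant columns carry no signal
  if (!any(keep)) return(y)
  cd <- cd[, keep, drop = FALSE]
  qrc <- qr(cd)
  if (qrc$rank < ncol(cd)) {
    bad <- colnames(confounds)[keep][qrc$pivot[(qrc$rank + 1L):ncol(cd)]]
    stop(sprintf("confound matrix is rank deficient (collinear: %s)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrc, t(y@values))       # P x N, intercept implicit (means)
  fitted <- cd %*% beta                   # T x N, column means are zero
  new("TimeSeriesMatrix", values = y@values - t(fitted),
      voxelIndex = y@voxelIndex, gridDim = y@gridDim, tr = y@tr)
}
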