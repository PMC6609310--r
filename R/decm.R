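#' Sliding-window dynamic eigenvector centrality mapping
#'
#' Given N voxel time series of length T and a requested number of maps M,
#' moves a window of W = T - M + 1 volumes over all M positions (step one
#' volume) and computes a scaled eigenvector centrality map per position.
#' Rows are renormalized within each window so every window's implicit
#' connectivity matrix is that window's correlation matrix plus one. With
#' M = 1 this reduces to the static centrality map over all T volumes.
#'
#' @param y a [TimeSeriesMatrix-class] or numeric N x T matrix
#' @param m number of centrality maps; requires 1 <= m <= T - 2 so that
#'   W >= 3 (with W = 2 all correlations are degenerate)
#' @param tol,maxIter power-iteration controls, see [ecmPowerIteration()]
#' @param targetMean per-map mean-intensity scaling, see [scaleCentrality()]
#' @return a [CentralitySeries-class] (N x m)
#' @export
slidingWindowEcm <- function(y, m, tol = 1e-9, maxIter = 1000L,
                             targetMean = 4500) {
  vals <- if (is(y, "TimeSeriesMatrix")) y@values else as.matrix(y)
  tr <- if (is(y, "TimeSeriesMatrix")) y@tr else 0
  tl <- ncol(vals)
  m <- as.integer(m)
  if (m < 1L) stop("m must be at least 1", call. = FALSE)
  if (m > tl - 2L)
    stop(sprintf(
      "window too short: m = %d with T = %d gives W = %d; need T >= m + 2",
      m, tl, tl - m + 1L), call. = FALSE)
  w <- tl - m + 1L
  n <- nrow(vals)
  out <- matrix(0, nrow = n, ncol = m)
  iters <- integer(m)
  conv <- logical(m)
  for (j in seq_len(m)) {
    ns <- normalizeRows(vals[, j:(j + w - 1L), drop = FALSE])
    cv <- ecmPowerIteration(ns, tol = tol, maxIter = maxIter)
    out[, j] <- scaleCentrality(cv, targetMean)
    iters[j] <- cv@iterations
    conv[j] <- cv@converged
  }
  new("CentralitySeries", values = out, windowLength = w,
      windowStarts = 0:(m - 1L), tr = tr, iterations = iters,
      converged = conv, targetMean = targetMean)
}

#' Reassemble a centrality series as a 4D image
#'
#' Each window position becomes one volume; out-of-mask voxels are 0.
#'
#' @param cs a [CentralitySeries-class]
#' @param mask the [Mask3D-class] the series was extracted with
#' @return a [Volume4D-class] with M volumes
#' @export
centralitySeriesToVolume <- function(cs, mask) {
  stopifnot(is(cs, "CentralitySeries"), is(mask, "Mask3D"))
  if (nrow(cs@values) != sum(mask@data))
    stop_shape("series rows (%d) do not match mask count (%d)",
               nrow(cs@values), sum(mask@data))
  insertMap(cs@values, mask, fill = 0, tr = cs@tr)
}
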