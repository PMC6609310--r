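#' Demean and unit-normalize window rows
#'
#' Prepares an N x W window for matrix-free centrality computation: each row
#' is demeaned and scaled to unit Euclidean norm, so the implicit matrix
#' rows %*% t(rows) is exactly the window's Pearson correlation matrix R.
#' Zero-variance rows are set to zero and recorded as degenerate rather than
#' dropped, keeping voxel indexing stable across windows.
#'
#' @param window numeric N x W matrix, W >= 3
#' @return a [NormalizedSeries-class]
#' @export
normalizeRows <- function(window) {
  window <- as.matrix(window)
  if (ncol(window) < 3L)
    stop(sprintf("window too short: W = %d, need at least 3", ncol(window)),
         call. = FALSE)
  ctr <- window - rowMeans(window)
  nrm <- sqrt(.rowSums(ctr^2, nrow(ctr), ncol(ctr)))
  degen <- which(nrm == 0)
  nrm[nrm == 0] <- 1
  out <- ctr / nrm
  if (length(degen)) out[degen, ] <- 0
  new("NormalizedSeries", rows = out, degenerateRows = as.integer(degen))
}

#' Eigenvector centrality by matrix-free power iteration
#'
#' Computes the dominant eigenvector of the connectivity matrix R + 1, where
#' R is the window's voxelwise Pearson correlation matrix, without ever
#' forming the N x N matrix: with unit-norm demeaned rows Y, each product is
#' evaluated as (R + 1) v = Y (t(Y) v) + sum(v) * 1, so peak working memory
#' stays O(NW). Adding the all-ones matrix makes every entry of R + 1
#' nonnegative (correlations are >= -1), so by Perron-Frobenius the dominant
#' eigenvector is nonnegative and power iteration from a uniform start
#' converges to it. Degenerate (zero-variance) rows get centrality 0.
#'
#' @param s a [NormalizedSeries-class]
#' @param tol convergence tolerance on the Euclidean norm of the change
#'   between successive normalized iterates (default 1e-9)
#' @param maxIter iteration cap (default 1000); non-convergence returns the
#'   last iterate with `converged = FALSE` and a warning
#' @return a [CentralityVector-class]
#' @export
ecmPowerIteration <- function(s, tol = 1e-9, maxIter = 1000L) {
  stopifnot(is(s, "NormalizedSeries"), tol > 0, maxIter >= 1L)
  n <- nrow(s@rows)
  degen <- s@degenerateRows
  live <- if (length(degen)) setdiff(seq_len(n), degen) else seq_len(n)
  if (length(live) < 2L)
    stop("need at least 2 non-degenerate rows", call. = FALSE)
  y <- s@rows[live, , drop = FALSE]
  v <- rep(1 / sqrt(length(live)), length(live))
  lambda <- NA_real_
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    w <- as.vector(y %*% crossprod(y, v)) + sum(v)
    lambda <- sqrt(sum(w^2))          # ||Av|| with unit v
    w <- w / lambda
    delta <- sqrt(sum((w - v)^2))
    v <- w
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("power iteration did not converge in %d iterations",
                    maxIter))
  out <- numeric(n)
  out[live] <- pmax(v, 0)             # clip Perron-cone round-off
  new("CentralityVector", values = out, eigenvalue = lambda,
      iterations = iter, converged = converged)
}

#' Scale a centrality vector to a target mean intensity
#'
#' Multiplies the unit-norm centrality vector so that its mean over all mask
#' voxels equals `targetMean` exactly (default 4500, a conventional map
#' intensity level). A positive rescaling, so voxel ordering is preserved.
#'
#' @param v a [CentralityVector-class] or numeric vector
#' @param targetMean desired mean intensity, > 0
#' @return numeric vector with mean exactly `targetMean`
#' @export
scaleCentrality <- function(v, targetMean = 4500) {
  vals <- if (is(v, "CentralityVector")) v@values else as.numeric(v)
  stopifnot(targetMean > 0)
  m <- mean(vals)
  if (m <= 0) stop("cannot scale an all-zero centrality vector", call. = FALSE)
  vals * (targetMean / m)
}
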