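#' Median split of subject ages
#'
#' Subjects strictly below the median age are labelled `"young"`, subjects
#' at or above it `"old"` (ties at the median go to the older group).
#'
#' @param ages numeric vector, one value per subject
#' @return character vector of labels with a `counts` attribute
#' @export
medianSplit <- function(ages) {
  stopifnot(length(ages) >= 2L)
  if (length(unique(ages)) == 1L)
    stop("degenerate split: all ages identical", call. = FALSE)
  med <- median(ages)
  lab <- ifelse(ages < med, "young", "old")
  structure(lab, counts = c(young = sum(lab == "young"),
                            old = sum(lab == "old")))
}

#' Construct a two-group design with optional covariates
#'
#' Builds the design matrix [intercept | group indicator | covariates] with
#' a contrast on the group indicator, testing level-2 minus level-1 of
#' `group`. Negate the contrast (see [flipContrast()]) for the opposite
#' direction. Covariates (e.g. scan length) are demeaned.
#'
#' @param group factor or character with exactly two levels
#' @param covariates optional numeric vector or matrix of nuisance
#'   covariates, one row per subject
#' @param labels optional subject identifiers
#' @return a [GroupDesign-class]
#' @export
groupDesign <- function(group, covariates = NULL, labels = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("group must have exactly two levels", call. = FALSE)
  n <- length(group)
  x <- cbind(intercept = 1, group = as.numeric(group == levels(group)[2L]))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n)
      stop_shape("covariate rows (%d) do not match subjects (%d)",
                 nrow(cv), n)
    cv <- sweep(cv, 2L, colMeans(cv))
    if (is.null(colnames(cv)))
      colnames(cv) <- paste0("covariate", seq_len(ncol(cv)))
    x <- cbind(x, cv)
  }
  if (is.null(labels)) labels <- paste0("sub", seq_len(n))
  new("GroupDesign", design = x,
      contrast = c(0, 1, rep(0, ncol(x) - 2L)),
      labels = as.character(labels))
}

#' Reverse the tested direction of a design's contrast
#' @param d a [GroupDesign-class]
#' @return the design with its contrast negated
#' @export
flipContrast <- function(d) {
  stopifnot(is(d, "GroupDesign"))
  new("GroupDesign", design = d@design, contrast = -d@contrast,
      labels = d@labels)
}

#' Voxelwise GLM contrast t-statistics
#'
#' Ordinary least squares per voxel; t = (c'beta) / se(c'beta) with
#' subjects - P residual degrees of freedom. Voxels with zero residual
#' variance get t = 0 (counted in a single warning).
#'
#' @param maps subjects x N matrix of per-subject voxel values
#' @param d a [GroupDesign-class]
#' @return length-N vector of t-statistics
#' @export
glmContrastTmap <- function(maps, d) {
  stopifnot(is(d, "GroupDesign"))
  x <- d@design
  if (nrow(maps) != nrow(x))
    stop_shape("map rows (%d) do not match design rows (%d)",
               nrow(maps), nrow(x))
  xtxi <- chol2inv(chol(crossprod(x)))
  beta <- xtxi %*% crossprod(x, maps)              # P x N
  res <- maps - x %*% beta
  dof <- nrow(x) - ncol(x)
  rss <- .colSums(res^2, nrow(res), ncol(res))
  ctr <- sweep(maps, 2L, colMeans(maps))
  tss <- .colSums(ctr^2, nrow(ctr), ncol(ctr))
  sigma2 <- rss / dof
  cvar <- as.numeric(t(d@contrast) %*% xtxi %*% d@contrast)
  num <- as.vector(crossprod(d@contrast, beta))
  se <- sqrt(cvar * sigma2)
  t <- numeric(ncol(maps))
  # a voxel whose residual variance vanishes (to round-off, relative to its
  # total variance) carries no usable error estimate: report t = 0
  ok <- tss > 0 & rss > 1e-24 * tss
  t[ok] <- num[ok] / se[ok]
  if (any(!ok))
    warning(sprintf("%d voxel(s) with zero residual variance; t set to 0",
                    sum(!ok)))
  t
}

#' TFCE parameter bundle
#'
#' @param eExponent extent exponent E (default 0.5)
#' @param hExponent height exponent H (default 2)
#' @param dh integration step; `NA` (default) uses max(|stat|)/100 per map
#' @param connectivity 6, 18 or 26 (default 26)
#' @return a [TfceParams-class]
#' @export
tfceParams <- function(eExponent = 0.5, hExponent = 2, dh = NA_real_,
                       connectivity = 26L) {
  new("TfceParams", eExponent = eExponent, hExponent = hExponent,
      dh = as.numeric(dh), connectivity = as.integer(connectivity))
}

#' Threshold-free cluster enhancement of a masked statistic map
#'
#' For each voxel, integrates e(h)^E * h^H over thresholds h below the
#' voxel's statistic, where e(h) is the size of the suprathreshold connected
#' component containing the voxel (discretized with step `dh`). Positive and
#' negative values are enhanced separately (the negative part on the negated
#' map) and re-signed.
#'
#' @param stat length-N statistic vector on the mask's voxels
#' @param mask [Mask3D-class] defining the 3D geometry
#' @param params a [TfceParams-class]
#' @return length-N enhanced statistics
#' @export
tfce <- function(stat, mask, params = tfceParams()) {
  stopifnot(is(mask, "Mask3D"), is(params, "TfceParams"))
  n <- sum(mask@data)
  if (length(stat) != n)
    stop_shape("stat length (%d) does not match mask count (%d)",
               length(stat), n)
  if (!all(is.finite(stat))) stop("non-finite statistics", call. = FALSE)
  dh <- params@dh
  if (is.na(dh)) {
    top <- max(abs(stat))
    if (top == 0) return(numeric(n))
    dh <- top / 100
  }
  # crop to the mask's bounding box: out-of-mask voxels are background and
  # cannot join any component, so enhancement on the subgrid is exact
  co <- arrayInd(which(mask@data), dim(mask))
  lo <- apply(co, 2L, min)
  hi <- apply(co, 2L, max)
  sub <- as.integer(hi - lo + 1L)
  idx <- as.vector((co[, 3L] - lo[3L]) * sub[1L] * sub[2L] +
                     (co[, 2L] - lo[2L]) * sub[1L] + (co[, 1L] - lo[1L] + 1L))
  grid <- numeric(prod(sub))
  enh <- numeric(n)
  for (sgn in c(1, -1)) {
    part <- pmax(sgn * stat, 0)
    if (!any(part > 0)) next
    grid[] <- 0
    grid[idx] <- part
    e <- .cpp_tfce(grid, sub, params@eExponent,
                   params@hExponent, dh, params@connectivity)
    enh <- enh + sgn * e[idx]
  }
  enh
}

# all permutations of 1..n (used when n! <= nPerm); n is small by then
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Permutation inference with TFCE and max-statistic FWE control
#'
#' Observed pipeline: voxelwise contrast t-map, then TFCE. Under each
#' permutation the data are re-labelled with the Freedman-Lane scheme
#' (fitted nuisance part kept, residuals permuted), the pipeline is
#' recomputed and the image-wide maximum enhanced statistic stored; the
#' corrected p-value of a voxel is (1 + #\{null max >= observed\}) /
#' (1 + nPerm), so p is never 0 and FWE control is location independent.
#' Inference is one-directional in the design's contrast; run
#' [flipContrast()] for the other direction.
#'
#' If fewer distinct permutations than `nPerm` exist, all of them are
#' enumerated instead (with a message).
#'
#' @param maps subjects x N matrix (N = in-mask voxels)
#' @param d a [GroupDesign-class]; columns with zero contrast weight are
#'   treated as nuisance for the Freedman-Lane residualization
#' @param mask [Mask3D-class] geometry for TFCE
#' @param params a [TfceParams-class]
#' @param nPerm number of permutations (>= 100)
#' @param seed integer RNG seed; results are reproducible given
#'   (data, design, seed, nPerm)
#' @param method `"freedman_lane"` (default) or `"labels"` (plain
#'   permutation of subject rows, ignoring nuisance structure)
#' @return a [PermutationResult-class]
#' @export
permutationFwe <- function(maps, d, mask, params = tfceParams(),
                           nPerm = 1000L, seed = 1L,
                           method = c("freedman_lane", "labels")) {
  stopifnot(is(d, "GroupDesign"), is(mask, "Mask3D"))
  method <- match.arg(method)
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) stop("nPerm must be at least 100", call. = FALSE)
  ns <- nrow(maps)
  if (ns != nrow(d@design))
    stop_shape("map rows (%d) do not match design rows (%d)",
               ns, nrow(d@design))
  tobs <- suppressWarnings(glmContrastTmap(maps, d))
  eobs <- tfce(tobs, mask, params)

  nuis <- which(d@contrast == 0)
  if (method == "freedman_lane" && length(nuis)) {
    z <- d@design[, nuis, drop = FALSE]
    hz <- z %*% chol2inv(chol(crossprod(z))) %*% t(z)
    fitted_z <- hz %*% maps
    resid_z <- maps - fitted_z
  } else {
    fitted_z <- NULL
  }

  exhaustive <- FALSE
  nfact <- suppressWarnings(factorial(ns))
  if (is.finite(nfact) && nfact <= nPerm) {
    perms <- .all_perms(ns)
    nPerm <- nrow(perms)
    exhaustive <- TRUE
    message(sprintf(
      "only %d distinct permutations exist; enumerating all of them", nPerm))
  } else {
    set.seed(seed)
    perms <- t(replicate(nPerm, sample.int(ns)))
  }

  nullMax <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    p <- perms[b, ]
    yb <- if (is.null(fitted_z)) maps[p, , drop = FALSE]
          else fitted_z + resid_z[p, , drop = FALSE]
    tb <- suppressWarnings(glmContrastTmap(yb, d))
    eb <- tfce(tb, mask, params)
    nullMax[b] <- max(eb, 0)
  }
  pcorr <- (1 + vapply(eobs, function(e) sum(nullMax >= e), numeric(1))) /
    (1 + nPerm)
  pcorr <- pmin(pcorr, 1)
  new("PermutationResult", tmap = tobs, tfceMap = eobs, pcorr = pcorr,
      nullMax = nullMax, nPerm = nPerm, seed = as.integer(seed),
      exhaustive = exhaustive)
}

#' Bonferroni threshold across networks
#'
#' Testing K resting-state networks separately multiplies the family of
#' tests; this returns the adjusted significance threshold alpha / k used
#' as an optional reporting layer (e.g. 0.05 / 10 = 0.005).
#'
#' @param alpha nominal significance level
#' @param kNetworks number of networks tested
#' @return adjusted threshold
#' @export
acrossNetworkCorrection <- function(alpha = 0.05, kNetworks) {
  stopifnot(kNetworks >= 1)
  alpha / kNetworks
}

#' Report suprathreshold clusters
#'
#' Connected components of \{pcorr < alpha\} within the mask, keeping only
#' clusters of more than `minSize` voxels; reports extent, peak statistic
#' and peak grid location.
#'
#' @param pcorr length-N corrected p-values on the mask's voxels
#' @param stat length-N statistics (for peak reporting)
#' @param mask [Mask3D-class] geometry
#' @param alpha significance threshold (default 0.05)
#' @param minSize minimum cluster extent; clusters must exceed it
#'   (default 10)
#' @param connectivity 6, 18 or 26 (default 26)
#' @return data.frame with one row per reported cluster (possibly empty)
#' @export
clusterReport <- function(pcorr, stat, mask, alpha = 0.05, minSize = 10L,
                          connectivity = 26L) {
  stopifnot(is(mask, "Mask3D"), alpha > 0, alpha < 1, minSize >= 1)
  n <- sum(mask@data)
  stopifnot(length(pcorr) == n, length(stat) == n)
  d <- dim(mask)
  idx <- which(mask@data)
  sig <- logical(prod(d))
  sig[idx[pcorr < alpha]] <- TRUE
  labs <- .cpp_label3d(sig, as.integer(d), as.integer(connectivity))
  vlab <- labs[idx]
  out <- data.frame(cluster = integer(), size = integer(),
                    peak_stat = numeric(), peak_x = integer(),
                    peak_y = integer(), peak_z = integer(),
                    min_pcorr = numeric())
  if (!any(vlab > 0)) return(out)
  for (l in sort(unique(vlab[vlab > 0]))) {
    sel <- which(vlab == l)
    if (length(sel) <= minSize) next
    peak <- sel[which.max(stat[sel])]
    co <- arrayInd(idx[peak], d)
    out <- rbind(out, data.frame(
      cluster = nrow(out) + 1L, size = length(sel),
      peak_stat = stat[peak], peak_x = co[1L], peak_y = co[2L],
      peak_z = co[3L], min_pcorr = min(pcorr[sel])))
  }
  out
}
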