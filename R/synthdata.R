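#' Synthetic cohort configuration
#'
#' Defines a multi-subject synthetic resting-state data set with K planted
#' networks (Gaussian spatial blobs), per-network latent signals whose
#' within-network coupling drifts slowly over the scan, and a between-group
#' difference in the temporal variability of that coupling on one network.
#' This is the statistical structure the centrality-dynamics analysis
#' assumes: networks whose connection strength varies in time, with one
#' group showing more variable within-network coupling than the other.
#'
#' Defaults describe the package's reference study conditions: a 20 x 20 x 12
#' grid, T = 120 volumes, three networks, baseline coupling 0.5, coupling
#' drift SD 0.15 in group A versus 0.30 in group B (a 2x variability ratio)
#' on the effect network, 10 subjects per group.
#'
#' @param grid X, Y, Z grid shape
#' @param nTime number of volumes per subject
#' @param nNetworks number of planted networks
#' @param blobCenters K x 3 matrix of blob centres (defaults spread over the
#'   grid)
#' @param blobWidth Gaussian sigma of the blobs in voxels
#' @param couplingMean baseline within-network coupling, in (0, 1)
#' @param couplingSd length-2 coupling-drift SD (group A, group B) on the
#'   effect network
#' @param couplingSdNull coupling-drift SD of all other networks
#' @param effectNetwork index of the network carrying the group difference;
#'   0 plants no group effect (null cohort)
#' @param noiseSd white observation-noise SD
#' @param nPerGroup subjects per group
#' @param tr repetition time in seconds
#' @param seed master seed; everything derives deterministically from it
#' @return a [SynthConfig-class]
#' @export
synthConfig <- function(grid = c(20L, 20L, 12L), nTime = 120L,
                        nNetworks = 3L, blobCenters = NULL, blobWidth = 2.5,
                        couplingMean = 0.5, couplingSd = c(0.15, 0.3),
                        couplingSdNull = 0.15, effectNetwork = 1L,
                        noiseSd = 0.4, nPerGroup = 10L, tr = 2.5,
                        seed = 42L) {
  grid <- as.integer(grid)
  if (is.null(blobCenters)) {
    # default: centres spread over the grid interior
    frac <- cbind(c(0.3, 0.7, 0.3, 0.7, 0.5),
                  c(0.3, 0.7, 0.7, 0.3, 0.5),
                  c(0.4, 0.6, 0.6, 0.4, 0.5))
    if (nNetworks > nrow(frac))
      stop("supply blobCenters explicitly for more than 5 networks",
           call. = FALSE)
    blobCenters <- round(frac[seq_len(nNetworks), , drop = FALSE] *
                           rep(grid, each = nNetworks))
  }
  new("SynthConfig", grid = grid, nTime = as.integer(nTime),
      nNetworks = as.integer(nNetworks),
      blobCenters = as.matrix(blobCenters), blobWidth = blobWidth,
      couplingMean = couplingMean, couplingSd = couplingSd,
      couplingSdNull = couplingSdNull,
      effectNetwork = as.integer(effectNetwork), noiseSd = noiseSd,
      nPerGroup = as.integer(nPerGroup), tr = tr, seed = as.integer(seed))
}

# raw (unit-peak) Gaussian blob loadings, one column per network
.blob_loadings <- function(cfg) {
  g <- cfg@grid
  co <- expand.grid(x = seq_len(g[1L]), y = seq_len(g[2L]),
                    z = seq_len(g[3L]))
  sapply(seq_len(cfg@nNetworks), function(k) {
    d2 <- (co$x - cfg@blobCenters[k, 1L])^2 +
      (co$y - cfg@blobCenters[k, 2L])^2 +
      (co$z - cfg@blobCenters[k, 3L])^2
    exp(-d2 / (2 * cfg@blobWidth^2))
  })
}

#' Analysis mask of a synthetic cohort
#'
#' The full grid: synthetic voxels outside the planted networks carry pure
#' noise, standing in for non-network gray matter.
#'
#' @param cfg a [SynthConfig-class]
#' @return a [Mask3D-class]
#' @export
synthMask <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  new("Mask3D", data = array(TRUE, dim = cfg@grid),
      affine = diag(c(3, 3, 3, 1)))
}

#' Generate the planted network templates
#'
#' Gaussian-blob spatial maps, Z-scored over the analysis mask (mean 0,
#' SD 1), mimicking the Z-valued network templates used as the spatial
#' dual-regression design. Deterministic given the configuration.
#'
#' @param cfg a [SynthConfig-class]
#' @param zthreshold Z threshold stored for network-mask derivation
#'   (default 3.0)
#' @return a [TemplateSet-class]
#' @export
generateTemplates <- function(cfg, zthreshold = 3.0) {
  stopifnot(is(cfg, "SynthConfig"))
  load <- .blob_loadings(cfg)
  dd <- as.matrix(stats::dist(cfg@blobCenters))
  diag(dd) <- Inf
  if (any(dd < cfg@blobWidth))
    warning("planted blobs overlap substantially")
  z <- scale(load)                      # columnwise mean 0, sd 1
  templateSet(z[, , drop = FALSE],
              names = paste0("network", seq_len(cfg@nNetworks)),
              zthreshold = zthreshold)
}

# standardized slow drift (mean 0, sd 1 over the scan): a random-direction
# linear trend carrying most of the variance plus a low-passed random walk.
# Dominated by the trend so that the drift amplitude resolvable by long
# sliding windows is nearly the same for every realization; a raw walk's
# resolvable amplitude varies several-fold between realizations, which would
# bury a between-group variability ratio under realization noise.
.std_walk <- function(tl) {
  ramp <- as.vector(scale(seq_len(tl)))
  w <- cumsum(rnorm(tl))
  k <- max(5L, tl %/% 3L)
  pad <- c(rev(w[seq_len(k)]), w, rev(w[tl - seq_len(k) + 1L]))
  s <- stats::filter(pad, rep(1 / k, k), sides = 2)[(k + 1L):(k + tl)]
  s <- as.vector(scale(as.vector(s)))
  sgn <- sample(c(-1, 1), 1L)
  as.vector(scale(sgn * sqrt(0.85) * ramp + sqrt(0.15) * s))
}

#' Generate one synthetic subject
#'
#' Each network carries a unit-variance latent signal; a voxel with blob
#' loading g in network k observes g * (c_k(t) * s_k(t) +
#' sqrt(1 - c_k(t)^2) * eta), so its marginal variance is constant and only
#' the within-network correlation moves with the coupling c_k(t). The
#' coupling drifts slowly over the scan (a standardized trend-dominated
#' drift, see the methods vignette) scaled by the group's coupling SD; white
#' observation noise and a baseline intensity of 1000 are added. Latent
#' signals and all noise are drawn from one seeded stream and the drift
#' shapes from a second, so changing only the coupling SDs changes only the
#' coupling trajectories (common random numbers across group-effect
#' settings).
#'
#' @param cfg a [SynthConfig-class]
#' @param group `"A"` or `"B"`
#' @param subjectSeed integer seed for this subject
#' @param nTime optional per-subject scan length (defaults to `cfg@nTime`)
#' @return list with `volume` (a [Volume4D-class]) and `truth` (latent
#'   courses, coupling trajectories, group, seed)
#' @export
generateSubject <- function(cfg, group = c("A", "B"), subjectSeed,
                            nTime = NULL) {
  stopifnot(is(cfg, "SynthConfig"))
  group <- match.arg(group)
  tl <- if (is.null(nTime)) cfg@nTime else as.integer(nTime)
  k <- cfg@nNetworks
  load <- .blob_loadings(cfg)
  nvox <- nrow(load)

  sds <- rep(cfg@couplingSdNull, k)
  if (cfg@effectNetwork > 0L)
    sds[cfg@effectNetwork] <-
      if (group == "A") cfg@couplingSd[1L] else cfg@couplingSd[2L]

  # stream 1: latent signals and every noise draw
  set.seed(subjectSeed)
  latent <- sapply(seq_len(k), function(j)
    as.vector(scale(rnorm(tl))))              # T x K, white, unit sd
  etas <- array(rnorm(nvox * tl * k), dim = c(nvox, tl, k))
  eps <- matrix(rnorm(nvox * tl), nvox, tl)

  # stream 2: standardized coupling-walk shapes (scaled by sds afterwards)
  set.seed((subjectSeed + 797L) %% 2147483629L)
  walks <- sapply(seq_len(k), function(j) .std_walk(tl))  # T x K

  coupling <- sapply(seq_len(k), function(j)
    pmin(pmax(cfg@couplingMean + sds[j] * walks[, j], 0.02), 0.98))

  sig <- matrix(0, nvox, tl)
  for (j in seq_len(k)) {
    shared <- latent[, j] * coupling[, j]            # T
    mixed <- matrix(shared, nvox, tl, byrow = TRUE) +
      etas[, , j] * matrix(sqrt(1 - coupling[, j]^2), nvox, tl, byrow = TRUE)
    sig <- sig + load[, j] * mixed
  }
  dat <- 1000 + sig + cfg@noiseSd * eps
  vol <- new("Volume4D", data = array(dat, dim = c(cfg@grid, tl)),
             voxelSize = c(3, 3, 3), affine = diag(c(3, 3, 3, 1)), tr = cfg@tr)
  list(volume = vol,
       truth = list(latent = t(latent), coupling = t(coupling),
                    group = group, seed = subjectSeed, nTime = tl))
}

#' Generate a balanced two-group synthetic cohort
#'
#' Per-subject seeds derive from the master seed, so the cohort is fully
#' reproducible; ages are drawn once (for median-split exercises) and scan
#' lengths may vary over a supplied set to exercise the scan-length
#' covariate.
#'
#' @param cfg a [SynthConfig-class]
#' @param scanLengths optional set of scan lengths to sample per subject
#'   (default: all subjects use `cfg@nTime`)
#' @return list with `subjects` (list of [generateSubject()] results),
#'   `design` (data.frame: subject, group, age, scan_length),
#'   `templates`, `mask` and `config`
#' @export
generateCohort <- function(cfg, scanLengths = NULL) {
  stopifnot(is(cfg, "SynthConfig"))
  n <- 2L * cfg@nPerGroup
  groups <- rep(c("A", "B"), each = cfg@nPerGroup)
  seeds <- derive_seeds(cfg@seed, n)
  set.seed(derive_seeds(cfg@seed, 1L, stream = 1L))
  ages <- round(rnorm(n, mean = 24.7, sd = 2.4), 1)
  tls <- if (is.null(scanLengths)) rep(cfg@nTime, n)
         else sample(as.integer(scanLengths), n, replace = TRUE)
  subjects <- lapply(seq_len(n), function(i)
    generateSubject(cfg, groups[i], seeds[i], nTime = tls[i]))
  design <- data.frame(subject = sprintf("sub%03d", seq_len(n)),
                       group = groups, age = ages, scan_length = tls,
                       stringsAsFactors = FALSE)
  list(subjects = subjects, design = design,
       templates = generateTemplates(cfg), mask = synthMask(cfg),
       config = cfg)
}
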