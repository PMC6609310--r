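#' Run the end-to-end centrality-dynamics pipeline
#'
#' Orchestrates the full analysis: input resolution (synthetic generation or
#' user-supplied files), optional motion residualization, sliding-window
#' centrality mapping, dual regression onto network templates, per-network
#' permutation inference with TFCE and FWE control, and group summary
#' curves. Stages communicate only through files (NIfTI/TSV) under `outDir`,
#' so each can be re-run or validated in isolation, and a manifest of MD5
#' hashes makes reproducibility checkable: identical config and seed give an
#' identical manifest.
#'
#' The configuration is a YAML (or pre-parsed list) with keys:
#' \describe{
#'   \item{seed}{integer; drives every random stage}
#'   \item{maps}{number of sliding-window maps M per subject}
#'   \item{target_mean}{centrality map intensity target (default 4500)}
#'   \item{zthreshold}{template Z threshold for network masks (default 3)}
#'   \item{synthetic}{optional block of [synthConfig()] arguments (grid,
#'     n_time, n_networks, coupling_mean, coupling_sd, coupling_sd_null,
#'     effect_network, noise_sd, n_per_group, tr); if present the cohort is
#'     generated}
#'   \item{design}{real-data mode: TSV with columns subject, file, group,
#'     age, scan_length and optionally motion (motion-parameter file)}
#'   \item{mask}{real-data mode: analysis mask NIfTI}
#'   \item{templates}{real-data mode: 4D template NIfTI; optional
#'     `template_names` file}
#'   \item{exclude_networks}{network names left out of testing (e.g. a
#'     cerebellar template)}
#'   \item{stats}{block: n_perm (default 1000), alpha (0.05), min_cluster
#'     (10), directions ("both", "positive" or "negative"), method
#'     (freedman_lane or labels)}
#' }
#'
#' @param config path to a YAML file, or an equivalent named list
#' @param outDir output directory (created if needed)
#' @return path to the written manifest, invisibly
#' @export
runPipeline <- function(config, outDir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("seed", "maps"))
    if (is.null(cfg[[key]]))
      stop(sprintf("config is missing required key '%s'", key), call. = FALSE)
  seed <- as.integer(cfg$seed)
  m <- as.integer(cfg$maps)
  target <- if (is.null(cfg$target_mean)) 4500 else cfg$target_mean
  zthr <- if (is.null(cfg$zthreshold)) 3.0 else cfg$zthreshold
  st <- cfg$stats
  nPerm <- if (is.null(st$n_perm)) 1000L else as.integer(st$n_perm)
  alpha <- if (is.null(st$alpha)) 0.05 else st$alpha
  minCl <- if (is.null(st$min_cluster)) 10L else as.integer(st$min_cluster)
  dirs <- if (is.null(st$directions)) "both" else st$directions
  meth <- if (is.null(st$method)) "freedman_lane" else st$method
  excl <- unlist(cfg$exclude_networks)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))
  outputs <- character()
  emit <- function(path) { outputs[[length(outputs) + 1L]] <<- path; path }

  ## stage 0: inputs
  if (!is.null(cfg$synthetic)) {
    sy <- cfg$synthetic
    sc <- synthConfig(
      grid = if (is.null(sy$grid)) c(20L, 20L, 12L) else unlist(sy$grid),
      nTime = if (is.null(sy$n_time)) 120L else sy$n_time,
      nNetworks = if (is.null(sy$n_networks)) 3L else sy$n_networks,
      blobWidth = if (is.null(sy$blob_width)) 2.5 else sy$blob_width,
      couplingMean = if (is.null(sy$coupling_mean)) 0.6 else sy$coupling_mean,
      couplingSd = if (is.null(sy$coupling_sd)) c(0.1, 0.2)
                   else unlist(sy$coupling_sd),
      couplingSdNull = if (is.null(sy$coupling_sd_null)) 0.1
                       else sy$coupling_sd_null,
      effectNetwork = if (is.null(sy$effect_network)) 1L
                      else sy$effect_network,
      noiseSd = if (is.null(sy$noise_sd)) 1 else sy$noise_sd,
      nPerGroup = if (is.null(sy$n_per_group)) 10L else sy$n_per_group,
      tr = if (is.null(sy$tr)) 2.5 else sy$tr,
      seed = seed)
    log_msg("generating synthetic cohort (%d subjects)", 2L * sc@nPerGroup)
    cohort <- generateCohort(sc,
      scanLengths = if (is.null(sy$scan_lengths)) NULL
                    else unlist(sy$scan_lengths))
    mask <- cohort$mask
    templates <- cohort$templates
    templates@zthreshold <- zthr
    design <- cohort$design
    synthDir <- file.path(outDir, "synth")
    dir.create(synthDir, showWarnings = FALSE)
    vols <- lapply(cohort$subjects, `[[`, "volume")
    for (i in seq_along(vols))
      emit(writeVolume4D(vols[[i]],
        file.path(synthDir, paste0(design$subject[i], ".nii"))))
    emit(writeVolume4D(mask, file.path(synthDir, "mask.nii")))
    tvol <- insertMap(templates@maps, mask)
    emit(writeVolume4D(tvol, file.path(synthDir, "templates.nii")))
    dpath <- file.path(synthDir, "design.tsv")
    write.table(design, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(dpath)
    motion <- rep(NA_character_, nrow(design))
  } else {
    for (key in c("design", "mask", "templates"))
      if (is.null(cfg[[key]]))
        stop(sprintf("config is missing required key '%s'", key),
             call. = FALSE)
    design <- read.table(cfg$design, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    need <- c("subject", "file", "group")
    miss <- setdiff(need, names(design))
    if (length(miss))
      stop(sprintf("design table lacks column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    mask <- asMask3D(readVolume4D(cfg$mask))
    templates <- readTemplateSet(cfg$templates, mask,
                                 names = cfg$template_names,
                                 zthreshold = zthr)
    vols <- lapply(design$file, readVolume4D)
    if (is.null(design$scan_length))
      design$scan_length <- vapply(vols, function(v) dim(v)[4L], numeric(1))
    motion <- if (is.null(design$motion)) rep(NA_character_, nrow(design))
              else design$motion
  }

  ## fail fast on window length before any heavy work
  for (i in seq_len(nrow(design))) {
    tl <- dim(vols[[i]])[4L]
    if (m > tl - 2L)
      stop(sprintf(
        "subject %s: %d maps requested but T = %d allows at most %d",
        design$subject[i], m, tl, tl - 2L), call. = FALSE)
  }

  ## stage 1-3: per-subject dECM and dual regression
  ecmDir <- file.path(outDir, "ecm")
  drDir <- file.path(outDir, "dualreg")
  dir.create(ecmDir, showWarnings = FALSE)
  dir.create(drDir, showWarnings = FALSE)
  nsub <- nrow(design)
  stage2 <- vector("list", nsub)
  courses <- vector("list", nsub)
  windowLengths <- integer(nsub)
  for (i in seq_len(nsub)) {
    ts <- extractTimeseries(vols[[i]], mask)
    if (!is.na(motion[i])) {
      log_msg("subject %s: residualizing motion", design$subject[i])
      ts <- regressConfounds(ts, readMotionTable(motion[i]))
    }
    cs <- slidingWindowEcm(ts, m, targetMean = target)
    windowLengths[i] <- cs@windowLength
    log_msg("subject %s: W = %d, mean iterations %.1f, converged %d/%d",
            design$subject[i], cs@windowLength, mean(cs@iterations),
            sum(cs@converged), m)
    emit(writeVolume4D(centralitySeriesToVolume(cs, mask),
      file.path(ecmDir, paste0(design$subject[i], "_ecm.nii"))))
    s1 <- stage1SpatialRegression(cs, templates)
    courses[[i]] <- s1
    sn <- normalizeTimecourses(s1)
    stage2[[i]] <- stage2TemporalRegression(cs, sn)
    cpath <- file.path(drDir, paste0(design$subject[i], "_timecourses.tsv"))
    write.table(data.frame(network = s1@names, s1@values), cpath,
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit(cpath)
    emit(writeVolume4D(insertMap(stage2[[i]]@values, mask),
      file.path(drDir, paste0(design$subject[i], "_maps.nii"))))
  }

  ## stage 4: per-network permutation inference
  statsDir <- file.path(outDir, "stats")
  dir.create(statsDir, showWarnings = FALSE)
  covar <- if (length(unique(design$scan_length)) > 1L)
    design$scan_length else NULL
  d <- groupDesign(design$group, covariates = covar,
                   labels = design$subject)
  directions <- switch(dirs, both = c("pos", "neg"), positive = "pos",
                       negative = "neg",
                       stop("stats.directions must be both/positive/negative",
                            call. = FALSE))
  tested <- setdiff(templates@names, excl)
  allClusters <- list()
  for (nm in tested) {
    k <- match(nm, templates@names)
    nmask <- suppressWarnings(makeNetworkMask(templates, k, mask))
    nk <- sum(nmask@data)
    if (nk < 2L) { log_msg("network %s: empty test mask, skipped", nm); next }
    sel <- templates@maps[, k] > templates@zthreshold
    ymat <- t(vapply(stage2, function(s) s@values[sel, k], numeric(nk)))
    for (dir in directions) {
      dd <- if (dir == "pos") d else flipContrast(d)
      pr <- permutationFwe(ymat, dd, nmask, nPerm = nPerm,
                           seed = seed + 131L * k +
                             ifelse(dir == "pos", 0L, 1L),
                           method = meth)
      base <- file.path(statsDir, sprintf("%s_%s", nm, dir))
      emit(writeVolume4D(insertMap(cbind(pr@tmap, pr@tfceMap, 1 - pr@pcorr),
                                   nmask), paste0(base, "_maps.nii")))
      cl <- clusterReport(pr@pcorr, pr@tmap, nmask, alpha = alpha,
                          minSize = minCl)
      if (nrow(cl))
        allClusters[[paste(nm, dir)]] <-
          cbind(network = nm, direction = dir, cl)
      cpath <- paste0(base, "_clusters.tsv")
      write.table(cl, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(cpath)
      log_msg("network %s (%s): min corrected p = %.4f, %d cluster(s)",
              nm, dir, min(pr@pcorr), nrow(cl))
    }
  }
  clTab <- if (length(allClusters)) do.call(rbind, allClusters) else
    data.frame(network = character(), direction = character())
  cpath <- file.path(statsDir, "clusters_all.tsv")
  write.table(clTab, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(cpath)

  ## stage 5: summaries
  sumDir <- file.path(outDir, "summary")
  dir.create(sumDir, showWarnings = FALSE)
  curves <- networkCurves(courses, design$group)
  emit(writeCurvesTable(curves, file.path(sumDir, "network_curves.tsv")))

  ## manifest
  manifest <- file.path(outDir, "manifest.tsv")
  rel <- sub(paste0("^", normalizePath(outDir), "/?"), "",
             normalizePath(unlist(outputs)))
  md5 <- unname(tools::md5sum(unlist(outputs)))
  mtab <- data.frame(file = rel, md5 = md5)
  mtab <- mtab[order(mtab$file), ]
  write.table(mtab, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("pipeline complete: %d outputs, manifest at %s",
          nrow(mtab), manifest)
  invisible(manifest)
}
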