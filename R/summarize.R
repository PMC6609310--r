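#' Winsorized mean
#'
#' Replaces the floor(trim * n) smallest values by the smallest retained
#' value and likewise at the top, then averages. With trim * n < 1 this is
#' the ordinary mean.
#'
#' @param values numeric vector (at least one value)
#' @param trim trimmed fraction per tail, in [0, 0.5)
#' @return the winsorized mean
#' @export
winsorizedMean <- function(values, trim = 0.1) {
  if (length(values) < 1L) stop("empty input", call. = FALSE)
  stopifnot(trim >= 0, trim < 0.5)
  n <- length(values)
  k <- floor(trim * n)
  if (k == 0L) return(mean(values))
  s <- sort(values)
  s[seq_len(k)] <- s[k + 1L]
  s[(n - k + 1L):n] <- s[n - k]
  mean(s)
}

#' Group mean centrality maps
#'
#' Time-averages each subject's centrality series over its windows, then
#' averages the resulting maps per group.
#'
#' @param series list of [CentralitySeries-class], one per subject
#' @param groups group label per subject
#' @return named list of length-N mean maps, one per group
#' @export
groupMeanEcm <- function(series, groups) {
  stopifnot(length(series) == length(groups))
  n <- nrow(series[[1L]]@values)
  subj <- vapply(series, function(s) {
    if (nrow(s@values) != n) stop_shape("subjects have different voxel counts")
    rowMeans(s@values)
  }, numeric(n))
  lapply(split(seq_along(groups), groups),
         function(i) rowMeans(subj[, i, drop = FALSE]))
}

#' Per-group network time-course curves with dispersion ribbons
#'
#' For each group, network and window position: the winsorized mean across
#' subjects and the across-subject standard deviation divided by
#' `ribbonScale` (a ribbon showing relative within-group variability).
#' Curves are meant to be computed on variance-unnormalized stage-1 time
#' courses so absolute centrality levels remain comparable across networks.
#'
#' @param timecourses list of [SubjectTimecourses-class], one per subject
#' @param groups group label per subject
#' @param trim winsorization fraction (default 0.1)
#' @param ribbonScale divisor of the standard deviation (default 5)
#' @return list with per-group `mean` and `ribbon` K x M matrices, plus
#'   `trim` and `ribbonScale`
#' @export
networkCurves <- function(timecourses, groups, trim = 0.1, ribbonScale = 5) {
  stopifnot(length(timecourses) == length(groups), ribbonScale > 0)
  k <- nrow(timecourses[[1L]]@values)
  m <- ncol(timecourses[[1L]]@values)
  for (tc in timecourses)
    if (nrow(tc@values) != k || ncol(tc@values) != m)
      stop_shape("subjects have mismatched network/window counts")
  groupsplit <- split(seq_along(groups), groups)
  res <- lapply(groupsplit, function(i) {
    arr <- vapply(timecourses[i], function(tc) tc@values, matrix(0, k, m))
    mu <- apply(arr, c(1L, 2L), winsorizedMean, trim = trim)
    if (length(i) < 2L) {
      warning("group with fewer than 2 subjects: ribbon set to 0")
      rib <- matrix(0, k, m)
    } else {
      rib <- apply(arr, c(1L, 2L), sd) / ribbonScale
    }
    rownames(mu) <- rownames(rib) <- timecourses[[1L]]@names
    list(mean = mu, ribbon = rib)
  })
  c(res, list(trim = trim, ribbonScale = ribbonScale))
}

#' Write network curves as a tidy TSV table
#'
#' @param curves result of [networkCurves()]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeCurvesTable <- function(curves, path) {
  groups <- setdiff(names(curves), c("trim", "ribbonScale"))
  rows <- do.call(rbind, lapply(groups, function(g) {
    mu <- curves[[g]]$mean
    rib <- curves[[g]]$ribbon
    data.frame(group = g,
               network = rep(rownames(mu), times = ncol(mu)),
               window = rep(seq_len(ncol(mu)) - 1L, each = nrow(mu)),
               mean = as.vector(mu), ribbon = as.vector(rib))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
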