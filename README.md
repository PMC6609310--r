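# decm — dynamic eigenvector centrality mapping for resting-state fMRI

Functional brain networks are not static: the strength of correlations
between regions drifts over the course of a resting-state fMRI scan. `decm`
measures that drift through the lens of *eigenvector centrality* (EC) — a
voxel's entry in the dominant eigenvector of the voxelwise connectivity
matrix, i.e. "a voxel is central when its neighbours are central" — and
tests whether the temporal behaviour of centrality differs between groups
of subjects. It is aimed at neuroimaging researchers who have co-registered
4D NIfTI data, a set of resting-state network (RSN) templates, and a
between-group question.

## What it computes

1. **Matrix-free ECM.** For unit-normalized, demeaned voxel time series
   `Y` (N × W), the connectivity matrix is `R + 1` with `R = Y Yᵀ` the
   Pearson correlation matrix (the +1 makes it nonnegative, so the dominant
   eigenvector is nonnegative by Perron–Frobenius). Power iteration uses

       (R + 1) v = Y (Yᵀ v) + sum(v) · 1,

   so the N × N matrix is never formed — memory stays O(N·W).
2. **Sliding window (dECM).** A window of `W = T − M + 1` volumes moves
   over all `M` positions, giving a time series of `M` centrality maps per
   subject, each rescaled to a mean intensity of 4500.
3. **Dual regression.** Each subject's centrality series is regressed
   spatially onto `K` RSN template Z-maps (one time course per network),
   then temporally onto those time courses (one correspondence map per
   network).
4. **Permutation inference.** Per-network GLM contrasts (group indicator +
   scan-length covariate) with threshold-free cluster enhancement (TFCE,
   `E = 0.5`, `H = 2`, 26-connectivity) and max-statistic family-wise error
   control under Freedman–Lane permutation; optional Bonferroni layer
   across networks (α/K) and cluster tables (extent > 10 voxels).
5. **Summaries.** Per-group mean ECM maps and winsorized-mean network time
   courses (trim 0.1, sd/5 ribbons).
6. **Synthetic cohorts.** A seeded generator plants Gaussian-blob networks
   with slowly drifting within-network coupling and a controllable
   between-group difference in coupling variability, so the entire pipeline
   is testable without any data download.

## Worked example

A synthetic cohort with a 2× coupling-variability difference planted in
network 1 (group B more variable), run through the full method:

```r
library(decm)

cfg <- synthConfig(seed = 42)      # 20x20x12 grid, T = 120, 10+10 subjects
cohort <- generateCohort(cfg)

## sliding-window centrality for one subject: 60 maps of 61 volumes
ts <- extractTimeseries(cohort$subjects[[1]]$volume, cohort$mask)
cs <- slidingWindowEcm(ts, m = 60)
cs
#> CentralitySeries: 4800 voxels x 60 windows (window length 61, TR 2.5 s)
#>   converged windows: 60/60; scaling target mean 4500

## dual regression of every subject onto the templates
stage2 <- lapply(cohort$subjects, function(s) {
  w <- slidingWindowEcm(extractTimeseries(s$volume, cohort$mask), 60)
  stage2TemporalRegression(w, normalizeTimecourses(
    stage1SpatialRegression(w, cohort$templates)))
})

## group inference inside the network-1 mask (contrast: group B - group A)
nmask <- makeNetworkMask(cohort$templates, 1, cohort$mask)
sel <- seriesValues(cohort$templates)[, 1] > 3
ymat <- t(sapply(stage2, function(s) seriesValues(s)[sel, 1]))
res <- permutationFwe(ymat, groupDesign(cohort$design$group), nmask,
                      nPerm = 500, seed = 1)
res
#> PermutationResult: 147 voxels, 500 permutations (seed 1)
#>   min corrected p: 0.005988
clusterReport(res@pcorr, res@tmap, nmask, alpha = 0.05, minSize = 10)
#>   cluster size peak_stat peak_x peak_y peak_z   min_pcorr
#> 1       1   58  4.524543      8      5      5 0.005988024
```

The planted network is flagged at FWE-corrected p ≈ 0.006: a 58-voxel
cluster peaking near the blob centre, where the more-variable group shows
stronger covariation of voxel centrality with the network's centrality
time course. The same run on a control network (no planted difference)
returns an empty cluster table.

The same analysis runs end to end from one config file:

```r
runPipeline(list(seed = 42, maps = 60,
                 synthetic = list(n_per_group = 10),
                 stats = list(n_perm = 500)), "out/")
```

writing per-stage NIfTI/TSV outputs and a `manifest.tsv` of MD5 hashes
(identical config + seed ⇒ identical manifest). A thin command-line
wrapper with subcommands (`mask`, `confound`, `run`, `dualreg`,
`pipeline`, ...) is installed at `exec/decm`.

## Documentation

The methods vignette (`vignettes/centrality-dynamics.Rmd`) documents the
model, the tunable parameters with their defaults and rationale, what the
synthetic generator does and does not emulate, numerical choices, and
known limitations.
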