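---
title: "Centrality dynamics: models, parameters and design choices"
author: "decm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(decm)
```

# The method

`decm` measures how voxelwise *eigenvector centrality* (EC) of a resting-state
fMRI network evolves over a scan, and tests whether the temporal behaviour of
that centrality differs between groups.

## Eigenvector centrality of the voxel graph

Treat every in-mask voxel as a node of a weighted graph whose edge weights
are the Pearson correlations between voxel time series, collected in the
N x N matrix **R**. A voxel's EC is its entry in the dominant eigenvector of
the connectivity matrix: a voxel is central when its neighbours are central.
Because correlations can be negative, the matrix actually used is **R** + 1
(every entry shifted by one), which is entrywise nonnegative; by the
Perron–Frobenius theorem its dominant eigenvector is nonnegative and unique
up to scale, so the centrality map is well defined.

At typical resolutions **R** cannot be stored (N² entries for tens of
thousands of voxels). With rows demeaned and scaled to unit Euclidean norm
collected in Y (N x W), we have **R** = Y Yᵀ, and a power-iteration step
factorizes as

    (R + 1) v  =  Y (Yᵀ v) + sum(v) · 1,

two thin matrix–vector products plus a rank-one term: peak memory stays
O(N·W) and the N x N matrix is never formed. `ecmPowerIteration()` starts
from the uniform vector (inside the Perron cone, so convergence to the
dominant eigenvector is guaranteed) and stops when the Euclidean change
between successive normalized iterates falls below `tol`.

Numerical choices:

* `tol = 1e-9`, `maxIter = 1000`. The +1 shift gives the matrix a large
  spectral gap, so typical window sizes converge in 10–30 iterations; a
  non-converged window is returned with `converged = FALSE` and a warning,
  never silently.
* Zero-variance (degenerate) rows are zeroed and *kept*, not dropped, so
  voxel indexing is stable across windows; their centrality is reported
  as 0.
* Round-off can push entries to tiny negatives; they are clipped to 0.
* Maps are rescaled by `scaleCentrality()` so the in-mask mean is exactly
  `targetMean` (default 4500, a conventional map intensity level). The
  scaling is positive, hence order-preserving and invertible.

## The sliding window

`slidingWindowEcm()` turns a T-volume series into M centrality maps: a
window of W = T − M + 1 volumes slides over all M positions in steps of one
volume (no stride parameter; the construct is "one map per possible
position"). Rows are renormalized *within each window*, so each window's
implicit matrix is exactly that window's correlation matrix plus one.
Subjects with different scan lengths get different window lengths for the
same M; the per-subject scan length is therefore carried into the group
model as a nuisance covariate. The minimum window is W = 3: with two
samples every correlation is ±1 and centrality is uninformative, which is
why `m ≤ T − 2` is enforced.

## Dual regression

Given K spatial network templates (Z-maps) sampled at the mask voxels,
`stage1SpatialRegression()` regresses every centrality map jointly on all
spatially demeaned templates, producing one time course per network per
subject; `stage2TemporalRegression()` then regresses every voxel's
centrality time course on all (variance-normalized) network time courses
plus an intercept, producing per-subject correspondence maps. Spatial
demeaning in stage 1 and the temporal intercept in stage 2 follow the
established dual-regression convention; variance normalization of stage-1
courses (default on, switchable) makes stage-2 coefficients comparable
across subjects. Joint (multiple) regression is the default in both stages;
with a single template the same code reduces to simple regression.

Per-network test masks are the voxels whose template Z exceeds
`zthreshold`, intersected with the analysis mask. The default threshold is
3.0 — a conventional Z cut for "inside the network" — and is configurable;
group statistics are evaluated only inside these masks. A cerebellar
template, when present, is accepted as input but left out of testing by
default (listed in `exclude_networks`).

## Group inference

`glmContrastTmap()` fits the per-voxel GLM (intercept, group indicator,
demeaned covariates) and forms contrast t-statistics. Voxels whose residual
variance vanishes relative to their total variance get t = 0, counted in a
warning. `tfce()` applies threshold-free cluster enhancement: each voxel's
statistic is replaced by the integral over thresholds h below it of
e(h)^E · h^H, where e(h) is the size of the suprathreshold connected
component containing the voxel. Defaults E = 0.5, H = 2 are the
enhancement's standard recommended settings; the integral is discretized
with `dh = max(|stat|)/100` per map, 26-connectivity. Positive and negative
parts are enhanced separately and re-signed.

`permutationFwe()` controls the family-wise error by the maximum statistic:
each permutation re-labels subjects, recomputes the t-map and its TFCE
enhancement, and stores the image-wide maximum; the corrected p-value is
(1 + #{null max ≥ observed}) / (1 + nPerm), never exactly zero. With a
nuisance covariate present, plain label permutation would break
exchangeability, so the default is the Freedman–Lane scheme: the fitted
nuisance part is kept fixed and the reduced-model residuals are permuted
(`method = "labels"` gives plain permutation). Inference is directional in
the design's contrast; the pipeline runs both directions by default.
When fewer distinct permutations exist than requested, all of them are
enumerated. Everything is reproducible bit for bit from
(data, design, seed, nPerm).

Testing K networks separately multiplies the family of tests;
`acrossNetworkCorrection()` provides the Bonferroni threshold α/K as an
optional reporting layer. `clusterReport()` lists connected components of
{p < α} larger than `minSize` (default 10) voxels.

## Summaries

`groupMeanEcm()` averages each subject's maps over windows and then over
subjects per group. `networkCurves()` plots-ready tables: per group,
network and window, the winsorized mean across subjects (trim 0.1; the
⌊trim·n⌋ most extreme values per tail are replaced by the nearest retained
value) and the across-subject standard deviation divided by 5 as a
dispersion ribbon. Curves are computed on variance-unnormalized stage-1
courses so that absolute centrality levels remain comparable across
networks.

# Mask construction

Four operations mirror a standard masking recipe:

* `buildGrayMatterMask()` — density strictly above a threshold
  (default 0.2);
* `buildFunctionalMask()` — per-voxel temporal minima strictly above a
  percentile of all minima (default 20th; linear-interpolation percentile).
  A voxel whose signal ever drops to background is thereby excluded;
* `combineGroupMasks()` — voxel kept when at least a fraction (default
  0.75, inclusive so that 3 of 4 subjects passes) of subject masks contain
  it;
* `intersectMasks()` — AND over masks, then AND NOT over exclusion masks
  (e.g. a user-supplied cerebellum mask; the package does not derive one).

Strict (>) comparisons at the density/percentile thresholds avoid admitting
exactly-zero background; the inclusive (≥) group fraction makes the
3-of-4 = 75% case well defined. Ties at a degenerate percentile (all minima
equal) are excluded by the strict rule. Grids are compared with a 1e-4
relative tolerance on affine entries, since resampled headers commonly
differ in last-digit noise. Warped masks are accepted as-is; the package
does not resample.

Motion residualization (`regressConfounds()`) fits each voxel on an
intercept plus the demeaned motion parameters and subtracts only the
motion part, preserving each voxel's temporal mean (the data's intensity
scale; correlation-based centrality is unaffected by the mean). No
derivative or squared expansions are added. The pipeline applies it after
masking — an ordering choice, as extraction and per-voxel regression
commute.

# The synthetic cohort generator

`generateCohort()` builds the multi-subject data set every stage is tested
against:

* **Space.** K Gaussian blobs on a small grid (default 20 × 20 × 12,
  σ = 2.5 voxels), Z-scored over the mask, serve as network templates. The
  analysis mask is the full grid; off-network voxels carry pure noise.
* **Signal.** Network k has a unit-variance white latent course s_k(t). A
  voxel with blob loading g observes
  g · (c_k(t) s_k(t) + √(1 − c_k(t)²) η) + noise, so its marginal variance
  is constant over time and *only the within-network correlation* moves
  with the coupling c_k(t) — the construct the analysis is meant to detect.
* **Dynamics.** The coupling drifts slowly around `couplingMean`
  (default 0.5) with per-scan standard deviation `couplingSd`, clamped to
  (0.02, 0.98). The drift shape is a standardized random-direction linear
  trend (85% of variance) plus a low-passed random walk (15%). The trend
  dominance is deliberate: the amplitude of a raw random walk that survives
  averaging by a long sliding window varies several-fold between
  realizations, which would drown a factor-two group difference in
  realization noise at realistic sample sizes; a trend-dominated drift is
  equally slow but its window-resolvable amplitude is nearly the same in
  every realization.
* **Group difference.** One designated network's coupling SD differs by
  group (defaults 0.15 vs 0.30 — a 2× variability ratio); all other
  networks share `couplingSdNull`. `effectNetwork = 0` yields a null
  cohort. Latent signals and noise come from one seeded stream and the
  drift shapes from another, with the SD applied after drawing, so changing
  only the group-effect knob changes only the coupling trajectories
  (common random numbers).
* **Realism limits.** No hemodynamic response, no physiological noise
  spectrum, no motion simulation, white observation noise (SD 0.4 against
  unit-amplitude network signal), baseline intensity 1000. Passing tests on
  this generator show the *pipeline machinery* is correct and calibrated;
  they do not show that real fMRI meets the generator's assumptions.

# Reference desk-scale study conditions

All heavier checks run at sizes chosen so the whole suite completes on one
CPU in minutes:

* *Type-I calibration*: 200 null cohorts on a 10 × 10 × 6 grid (K = 2,
  blob σ 1.5, T = 40, M = 20, 8 subjects per group), 500 permutations each,
  single contrast direction; the family-wise rejection rate at α = 0.05 is
  compared with the binomial band around 0.05.
* *Planted-effect recovery*: 20 cohorts at the generator defaults
  (20 × 20 × 12, T = 120, M = 60, 10 per group, 2× coupling-variability
  ratio), 500 permutations; the planted network must be flagged
  (FWE p < 0.05 inside its mask) in at least 80% of replicates while the
  control network stays clean.
* Production-scale inference would use 10000 permutations; 500 is ample for
  p ≈ 0.05 decisions at desk scale (Monte-Carlo SE ≈ 0.01).

# Known limitations

* The sliding window resolves only modulations slower than the window; the
  generator's trend-dominated drift respects this, and real dynamics faster
  than W volumes are invisible to the method by construction.
* One window length per subject couples M and T; comparing subjects with
  very different scan lengths relies on the scan-length covariate being an
  adequate adjustment.
* TFCE integration is discretized (dh = max/100); the single-peak closed
  form is reproduced to under 1%, and the same discretization is used for
  observed and permuted maps, so inference is internally consistent.
* Permutation inference assumes whole-cohort exchangeability (after
  Freedman–Lane residualization); no exchangeability blocks are
  implemented.
* NIfTI-2, CIFTI, surface data, spatial normalization, slice-timing and
  realignment are out of scope; inputs are assumed co-registered.
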