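test_that("median split puts the median and ties in the older group", {
  expect_equal(as.vector(medianSplit(c(20, 22, 24, 26))),
               c("young", "young", "old", "old"))
  odd <- medianSplit(c(20, 24, 28))
  expect_equal(as.vector(odd), c("young", "old", "old"))
  ties <- medianSplit(c(20, 24, 24, 24, 30))
  expect_equal(sum(ties == "old"), 4)
  expect_error(medianSplit(rep(24, 5)), "identical")
})

test_that("voxelwise contrast t equals the classical two-sample t", {
  set.seed(71)
  maps <- matrix(rnorm(6 * 5), 6, 5)
  d <- groupDesign(rep(c("a", "b"), each = 3))
  tmap <- glmContrastTmap(maps, d)
  for (v in 1:5) {
    tt <- t.test(maps[4:6, v], maps[1:3, v], var.equal = TRUE)
    expect_equal(tmap[v], unname(tt$statistic), tolerance = 1e-12)
  }
  # identical values in both groups: zero everywhere (with a warning)
  same <- matrix(rep(rnorm(5), each = 6), 6, 5)
  expect_warning(t0 <- glmContrastTmap(same, d), "zero residual")
  expect_equal(t0, rep(0, 5))
  # covariate identical to the group indicator is rank deficient
  expect_error(groupDesign(rep(c("a", "b"), each = 3),
                           covariates = rep(0:1, each = 3)),
               "rank deficient")
})

test_that("TFCE matches its closed forms", {
  mk <- full_mask(c(9, 9, 9))
  stat <- numeric(9^3)
  peak <- (4 * 81) + (4 * 9) + 5          # an interior voxel
  stat[peak] <- 2
  # isolated peak of height 2 with E = 0.5, H = 2: integral h^2 dh = 8/3
  e <- tfce(stat, mk, tfceParams(dh = 0.01))
  expect_equal(e[peak], 8 / 3, tolerance = 0.01)
  expect_true(all(e[-peak] == 0))
  # uniform 2x2x2 cube: e(h) = 8 at every level, so sqrt(8) times the peak
  stat8 <- numeric(9^3)
  cube <- as.vector(outer(outer(2:3, (2:3 - 1) * 9, "+"), (2:3 - 1) * 81, "+"))
  stat8[cube] <- 2
  e8 <- tfce(stat8, mk, tfceParams(dh = 0.01))
  expect_equal(e8[cube], rep(sqrt(8) * e[peak], 8), tolerance = 1e-10)
  # all-zero map stays zero, negative parts are re-signed
  expect_equal(tfce(numeric(9^3), mk), numeric(9^3))
  expect_equal(tfce(-stat, mk, tfceParams(dh = 0.01))[peak], -8 / 3,
               tolerance = 0.01)
})

test_that("TFCE is monotone and adjacency-equivariant", {
  mk <- full_mask(c(6, 6, 6))
  set.seed(72)
  for (i in 1:50) {
    a <- pmax(rnorm(216), 0)
    b <- a + runif(216, 0, 0.5)           # pointwise >= a
    pars <- tfceParams(dh = max(b) / 50)
    ea <- tfce(a, mk, pars)
    eb <- tfce(b, mk, pars)
    expect_true(all(eb - ea >= -1e-12))
  }
  # axis permutation preserves adjacency, so enhancement commutes with it
  set.seed(73)
  arr <- array(pmax(rnorm(216), 0), dim = c(6, 6, 6))
  e1 <- array(tfce(as.vector(arr), mk), dim = c(6, 6, 6))
  perm <- aperm(arr, c(2, 3, 1))
  e2 <- array(tfce(as.vector(perm), mk), dim = c(6, 6, 6))
  expect_equal(aperm(e1, c(2, 3, 1)), e2, tolerance = 1e-12)
})

test_that("component labelling agrees with an independent flood fill", {
  set.seed(74)
  for (conn in c(6L, 18L, 26L)) {
    m <- array(runif(6 * 5 * 4) < 0.35, dim = c(6, 5, 4))
    ours <- decm:::.cpp_label3d(as.vector(m), dim(m), conn)
    ref <- flood_fill_labels(m, conn)
    expect_equal(max(ours), max(ref))
    # same partition: labels must be a relabelling of each other
    expect_equal(length(unique(paste(ours[m], ref[m]))), max(ref))
  }
})

test_that("cluster reporting filters by extent and matches flood-fill sizes", {
  d <- c(10, 8, 6)
  mk <- full_mask(d)
  sig <- array(FALSE, dim = d)
  sig[1:3, 1:2, 1:2] <- TRUE            # 12 voxels
  sig[6:9, 5:6, 4] <- TRUE              # 8 voxels
  pc <- rep(1, prod(d))
  pc[which(sig)] <- 0.01
  stat <- seq_len(prod(d)) / prod(d)
  tab <- clusterReport(pc, stat, mk, alpha = 0.05, minSize = 10)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size, 12)
  ref <- flood_fill_labels(sig, 26L)
  expect_setequal(tabulate(ref[ref > 0]), c(12, 8))
  empty <- clusterReport(rep(1, prod(d)), stat, mk)
  expect_equal(nrow(empty), 0)
})

test_that("identical maps across subjects give corrected p of 1", {
  cfg <- small_cfg(75)
  nmask <- makeNetworkMask(generateTemplates(cfg), 1, synthMask(cfg))
  nk <- maskCount(nmask)
  set.seed(75)
  maps <- matrix(rep(rnorm(nk), each = 10), 10, nk)
  d <- groupDesign(rep(c("a", "b"), each = 5))
  pr <- suppressWarnings(permutationFwe(maps, d, nmask, nPerm = 100,
                                        seed = 5))
  expect_true(all(pr@pcorr == 1))
})

test_that("permutation inference is seed-reproducible and monotone", {
  cfg <- small_cfg(76)
  nmask <- makeNetworkMask(generateTemplates(cfg), 1, synthMask(cfg))
  nk <- maskCount(nmask)
  set.seed(76)
  maps <- matrix(rnorm(12 * nk), 12, nk) +
    outer(rep(c(0, 1), each = 6), rnorm(nk, sd = 0.5))
  d <- groupDesign(rep(c("a", "b"), each = 6),
                   covariates = rnorm(12))
  p1 <- permutationFwe(maps, d, nmask, nPerm = 200, seed = 9)
  p2 <- permutationFwe(maps, d, nmask, nPerm = 200, seed = 9)
  expect_identical(p1@pcorr, p2@pcorr)
  expect_identical(p1@nullMax, p2@nullMax)
  o <- order(p1@tfceMap, decreasing = TRUE)
  expect_true(!is.unsorted(p1@pcorr[o]))
  expect_true(all(p1@pcorr >= 1 / 201 & p1@pcorr <= 1))
})

test_that("small cohorts fall back to exhaustive enumeration", {
  cfg <- small_cfg(77)
  nmask <- makeNetworkMask(generateTemplates(cfg), 1, synthMask(cfg))
  nk <- maskCount(nmask)
  set.seed(77)
  maps <- matrix(rnorm(4 * nk), 4, nk)
  d <- groupDesign(rep(c("a", "b"), each = 2))
  expect_message(pr <- permutationFwe(maps, d, nmask, nPerm = 100, seed = 1),
                 "enumerating")
  expect_true(pr@exhaustive)
  expect_equal(pr@nPerm, 24L)   # 4! distinct permutations
})

test_that("the across-network Bonferroni layer scales the threshold", {
  expect_equal(acrossNetworkCorrection(0.05, 10), 0.005)
  expect_equal(acrossNetworkCorrection(0.05, 1), 0.05)
  ks <- 1:12
  expect_true(all(diff(acrossNetworkCorrection(0.05, ks)) < 0))
})
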