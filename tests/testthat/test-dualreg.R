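# build K orthogonal spatially-demeaned templates on n voxels
ortho_templates <- function(n, k, seed = 1) {
  set.seed(seed)
  raw <- matrix(rnorm(n * k), n, k)
  raw <- sweep(raw, 2, colMeans(raw))
  qr.Q(qr(raw))
}

test_that("stage 1 recovers known time courses exactly from noiseless maps", {
  n <- 200; k <- 3; m <- 12
  tpl <- ortho_templates(n, k, seed = 51)
  set.seed(52)
  strue <- matrix(rnorm(k * m), k, m)
  cs <- tpl %*% strue
  s <- stage1SpatialRegression(cs, templateSet(tpl))
  expect_equal(seriesValues(s), strue, tolerance = 1e-8)

  # single template: recovered course peaks where the pattern is injected
  one <- templateSet(tpl[, 1, drop = FALSE])
  amp <- c(0.1, 0.2, 5, 0.3)
  cs1 <- tpl[, 1, drop = FALSE] %*% matrix(amp, 1)
  s1 <- stage1SpatialRegression(cs1, one)
  expect_equal(which.max(seriesValues(s1)[1, ]), 3L)
})

test_that("noisy stage 1 matches the normal-equations oracle", {
  n <- 300; k <- 4; m <- 15
  tpl <- ortho_templates(n, k, seed = 53) %*% diag(seq(1, 2, length.out = k))
  set.seed(54)
  strue <- matrix(rnorm(k * m), k, m)
  cs <- tpl %*% strue + 0.1 * matrix(rnorm(n * m), n, m)
  s <- stage1SpatialRegression(cs, templateSet(tpl))
  # independent oracle: explicit normal equations on the same demeaned data
  cd <- sweep(tpl, 2, colMeans(tpl))
  yd <- sweep(cs, 2, colMeans(cs))
  oracle <- solve(t(cd) %*% cd, t(cd) %*% yd)
  expect_equal(seriesValues(s), unname(oracle), tolerance = 1e-8)
  for (j in seq_len(k))
    expect_gt(cor(seriesValues(s)[j, ], strue[j, ]), 0.99)
})

test_that("time-course variance normalization is exact and scale-free", {
  set.seed(55)
  s <- new("SubjectTimecourses", values = matrix(rnorm(3 * 20), 3, 20),
           varianceNormalized = FALSE, names = letters[1:3])
  n1 <- normalizeTimecourses(s)
  expect_equal(apply(seriesValues(n1), 1, sd), rep(1, 3), tolerance = 1e-12)
  s10 <- new("SubjectTimecourses", values = s@values * 10,
             varianceNormalized = FALSE, names = letters[1:3])
  expect_equal(seriesValues(normalizeTimecourses(s10)), seriesValues(n1))
  szero <- new("SubjectTimecourses",
               values = rbind(s@values[1:2, ], 7),
               varianceNormalized = FALSE, names = c("a", "b", "flat"))
  expect_error(normalizeTimecourses(szero), "flat")
})

test_that("stage 2 recovers spatial maps and matches its oracle", {
  n <- 250; k <- 3; m <- 20
  tpl <- ortho_templates(n, k, seed = 56)
  set.seed(57)
  strue <- matrix(rnorm(k * m), k, m)
  cs <- tpl %*% strue
  sc <- new("SubjectTimecourses", values = strue,
            varianceNormalized = FALSE, names = paste0("n", 1:k))
  maps <- stage2TemporalRegression(cs, sc)
  for (j in seq_len(k))
    expect_equal(cor(seriesValues(maps)[, j], tpl[, j]), 1, tolerance = 1e-8)

  # a voxel with no temporal variation gets all-zero coefficients
  cs2 <- cs; cs2[17, ] <- 42
  maps2 <- stage2TemporalRegression(cs2, sc)
  expect_equal(seriesValues(maps2)[17, ], rep(0, k), tolerance = 1e-10)

  # noisy oracle equivalence, voxelwise
  csn <- cs + 0.05 * matrix(rnorm(n * m), n, m)
  mapsn <- stage2TemporalRegression(csn, sc)
  x <- cbind(1, t(strue))
  oracle <- t(solve(t(x) %*% x, t(x) %*% t(csn)))[, -1]
  expect_equal(seriesValues(mapsn), unname(oracle), tolerance = 1e-8)
})

test_that("the full dual-regression round trip is faithful and order-invariant", {
  n <- 300; k <- 4; m <- 25
  tpl <- ortho_templates(n, k, seed = 58) %*% diag(c(3, 2.5, 2, 1.5))
  set.seed(59)
  strue <- matrix(rnorm(k * m), k, m)
  cs <- tpl %*% strue
  s1 <- stage1SpatialRegression(cs, templateSet(tpl))
  maps <- stage2TemporalRegression(cs, normalizeTimecourses(s1))
  for (j in seq_len(k)) {
    expect_gt(cor(seriesValues(s1)[j, ], strue[j, ]), 0.999)
    expect_gt(cor(seriesValues(maps)[, j], tpl[, j]), 0.999)
  }
  # permuting template columns permutes the outputs to match
  p <- c(3, 1, 4, 2)
  s1p <- stage1SpatialRegression(cs, templateSet(tpl[, p]))
  expect_equal(seriesValues(s1p), seriesValues(s1)[p, ], tolerance = 1e-8)
})

test_that("collinear designs fail with a diagnostic", {
  n <- 100
  tpl <- ortho_templates(n, 2, seed = 60)
  bad <- cbind(tpl, tpl[, 1] * 2 + tpl[, 2])
  cs <- matrix(rnorm(n * 8), n, 8)
  expect_error(stage1SpatialRegression(cs, templateSet(bad)), "collinear")
  sdup <- new("SubjectTimecourses",
              values = rbind(rnorm(8), rnorm(8))[c(1, 1), ],
              varianceNormalized = FALSE, names = c("a", "b"))
  expect_error(stage2TemporalRegression(cs, sdup), "collinear")
})

test_that("network masks apply the Z threshold inside the analysis mask", {
  cfg <- small_cfg(61)
  mask <- synthMask(cfg)
  tpl <- generateTemplates(cfg)
  nm <- makeNetworkMask(tpl, 1, mask)
  expect_equal(maskCount(nm), sum(seriesValues(tpl)[, 1] > 3))
  # threshold zero on a signed map keeps the positive support
  tpl0 <- templateSet(seriesValues(tpl), zthreshold = 0)
  nm0 <- makeNetworkMask(tpl0, 2, mask)
  expect_equal(maskCount(nm0), sum(seriesValues(tpl)[, 2] > 0))
  # threshold above the maximum yields an empty mask with a warning
  tplhi <- templateSet(seriesValues(tpl),
                       zthreshold = max(seriesValues(tpl)) + 1)
  expect_warning(nmhi <- makeNetworkMask(tplhi, 1, mask), "empty")
  expect_equal(maskCount(nmhi), 0)
})
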