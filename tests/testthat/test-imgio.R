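test_that("NIfTI write/read round-trips volumes bit-identically", {
  vol <- rand_volume(c(10, 10, 10), tl = 20, seed = 11)
  f <- withr::local_tempfile(fileext = ".nii")
  writeVolume4D(vol, f)
  back <- readVolume4D(f)
  expect_identical(imgData(back), imgData(vol))
  expect_equal(affineMat(back), affineMat(vol))
  expect_equal(repetitionTime(back), 2.5)
})

test_that("3D images are promoted to one volume and 5D files are rejected", {
  m <- rand_mask(c(5, 5, 5))
  f <- withr::local_tempfile(fileext = ".nii")
  writeVolume4D(m, f)
  v <- readVolume4D(f)
  expect_equal(dim(v)[4], 1)
  expect_setequal(unique(as.vector(imgData(v))), c(0, 1))

  f5 <- withr::local_tempfile(fileext = ".nii")
  im5 <- RNifti::asNifti(array(0, dim = c(3, 3, 3, 2, 2)))
  RNifti::writeNifti(im5, f5)
  expect_error(readVolume4D(f5), "dimensions")
  expect_error(readVolume4D("no/such/file.nii"), "no/such/file")
})

test_that("gray-matter mask thresholds density strictly", {
  d <- array(0, dim = c(3, 1, 1, 1))
  d[, 1, 1, 1] <- c(0.1, 0.25, 0.5)
  vol <- new("Volume4D", data = d, voxelSize = c(1, 1, 1),
             affine = diag(4), tr = 0)
  expect_equal(as.vector(imgData(buildGrayMatterMask(vol, 0.2))),
               c(FALSE, TRUE, TRUE))
  zero <- new("Volume4D", data = array(0, dim = c(4, 4, 4, 1)),
              voxelSize = c(1, 1, 1), affine = diag(4), tr = 0)
  expect_equal(maskCount(buildGrayMatterMask(zero)), 0)
  ones <- new("Volume4D", data = array(1, dim = c(4, 4, 4, 1)),
              voxelSize = c(1, 1, 1), affine = diag(4), tr = 0)
  expect_equal(maskCount(buildGrayMatterMask(ones)), 64)
  bad <- new("Volume4D", data = array(2, dim = c(4, 4, 4, 1)),
             voxelSize = c(1, 1, 1), affine = diag(4), tr = 0)
  expect_error(buildGrayMatterMask(bad), "\\[0, 1\\]")
})

test_that("functional mask keeps voxels above the percentile of minima", {
  set.seed(5)
  # distinct minima: add a distinct per-voxel offset
  base <- array(sample(seq_len(1000)), dim = c(10, 10, 10))
  d <- array(rnorm(1000 * 5, sd = 0.01), dim = c(10, 10, 10, 5)) +
    as.vector(base)
  vol <- new("Volume4D", data = d, voxelSize = c(1, 1, 1),
             affine = diag(4), tr = 1)
  mk <- buildFunctionalMask(vol, 20)
  expect_equal(maskCount(mk), 800)
  # brute-force check against an explicit sort of the minima
  mins <- apply(d, 1:3, min)
  expect_setequal(which(imgData(mk)), order(mins, decreasing = TRUE)[1:800])

  const <- new("Volume4D", data = array(7, dim = c(4, 4, 4, 3)),
               voxelSize = c(1, 1, 1), affine = diag(4), tr = 1)
  expect_equal(maskCount(buildFunctionalMask(const, 20)), 0)  # all tie

  one <- new("Volume4D", data = d[, , , 1, drop = FALSE],
             voxelSize = c(1, 1, 1), affine = diag(4), tr = 1)
  expect_equal(which(imgData(buildFunctionalMask(one, 20))),
               which(d[, , , 1] > quantile(d[, , , 1], 0.2)))
})

test_that("group mask combination uses an inclusive fraction", {
  d <- c(4, 4, 2)
  m1 <- full_mask(d)
  m0 <- new("Mask3D", data = array(FALSE, dim = d), affine = m1@affine)
  present3 <- combineGroupMasks(list(m1, m1, m1, m0), 0.75)
  expect_equal(maskCount(present3), prod(d))        # 3 of 4 = 0.75 included
  present2 <- combineGroupMasks(list(m1, m1, m0, m0), 0.75)
  expect_equal(maskCount(present2), 0)
  single <- rand_mask(d, seed = 9)
  expect_identical(imgData(combineGroupMasks(list(single), 0.3)),
                   imgData(single))
  # monotone: raising the fraction never adds voxels; idempotent on copies
  ms <- lapply(1:5, function(i) rand_mask(d, seed = i))
  prev <- prod(d) + 1
  for (f in c(0.2, 0.4, 0.6, 0.8, 1)) {
    ct <- maskCount(combineGroupMasks(ms, f))
    expect_lte(ct, prev)
    prev <- ct
  }
  expect_identical(imgData(combineGroupMasks(list(single, single), 0.9)),
                   imgData(single))
  bad <- rand_mask(c(4, 4, 3))
  expect_error(combineGroupMasks(list(m1, bad)), "different grids")
})

test_that("mask intersection honours exclusions", {
  d <- c(4, 4, 2)
  a <- rand_mask(d, seed = 1)
  b <- new("Mask3D", data = !imgData(a), affine = a@affine)
  expect_equal(maskCount(intersectMasks(list(a, b))), 0)
  expect_equal(maskCount(intersectMasks(list(a), list(a))), 0)
  expect_identical(imgData(intersectMasks(list(a, full_mask(d)))),
                   imgData(a))
})

test_that("extract and insert are exact inverses with x-fastest traversal", {
  vol <- rand_volume(c(6, 5, 4), tl = 7, seed = 3)
  mask <- rand_mask(c(6, 5, 4), seed = 4)
  ts <- extractTimeseries(vol, mask)
  expect_equal(nrow(seriesValues(ts)), maskCount(mask))
  back <- insertMap(seriesValues(ts), mask, fill = -99, tr = 2.5)
  inm <- imgData(mask)
  for (t in c(1, 7)) {
    expect_equal(imgData(back)[, , , t][inm], imgData(vol)[, , , t][inm])
    expect_true(all(imgData(back)[, , , t][!inm] == -99))
  }
  # round trip the other way: insert then extract
  set.seed(8)
  vals <- matrix(rnorm(maskCount(mask) * 3), ncol = 3)
  expect_equal(seriesValues(extractTimeseries(insertMap(vals, mask), mask)),
               vals)

  # traversal order: two known voxels, x varies fastest
  d <- c(3, 3, 2)
  mk <- new("Mask3D", data = array(FALSE, dim = d), affine = diag(4))
  mk@data[2, 1, 1] <- TRUE   # linear index 2
  mk@data[1, 2, 1] <- TRUE   # linear index 4
  grid <- array(seq_len(prod(d) * 2), dim = c(d, 2))
  v <- new("Volume4D", data = grid, voxelSize = c(1, 1, 1),
           affine = diag(4), tr = 1)
  got <- extractTimeseries(v, mk)
  expect_equal(seriesValues(got)[, 1], c(2, 4))
  expect_equal(voxelIndex(got), arrayInd(c(2L, 4L), d))

  expect_equal(nrow(seriesValues(extractTimeseries(vol, full_mask(c(6, 5, 4))))),
               6 * 5 * 4)
  empty <- new("Mask3D", data = array(FALSE, dim = c(6, 5, 4)),
               affine = diag(c(3, 3, 3, 1)))
  expect_error(extractTimeseries(vol, empty), "empty")
  expect_error(insertMap(matrix(0, 3, 2), mask), "match")
})
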