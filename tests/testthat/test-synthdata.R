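test_that("templates are Z-scored blobs peaking at their centres", {
  cfg <- synthConfig(grid = c(12, 12, 8), nNetworks = 1L,
                     blobCenters = matrix(c(6, 6, 4), 1), seed = 91)
  tpl <- generateTemplates(cfg)
  z <- seriesValues(tpl)[, 1]
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  centre <- (4 - 1) * 144 + (6 - 1) * 12 + 6
  expect_equal(which.max(z), centre)
  # well-separated blobs are nearly uncorrelated in space
  cfg2 <- synthConfig(grid = c(16, 16, 10), nNetworks = 2L,
                      blobWidth = 1.5, seed = 92)
  z2 <- seriesValues(generateTemplates(cfg2))
  expect_lt(abs(cor(z2[, 1], z2[, 2])), 0.1)
})

test_that("subjects are reproducible and noiseless coupling gives tight blobs", {
  cfg <- small_cfg(93)
  s1 <- generateSubject(cfg, "A", 12345L)
  s2 <- generateSubject(cfg, "A", 12345L)
  expect_identical(imgData(s1$volume), imgData(s2$volume))
  # noiseless, near-unit coupling: strong within-blob correlation
  cfgc <- synthConfig(grid = c(10, 10, 6), nTime = 60, nNetworks = 1L,
                      blobCenters = matrix(c(5, 5, 3), 1), blobWidth = 1.5,
                      couplingMean = 0.97, couplingSd = c(0, 0),
                      couplingSdNull = 0, noiseSd = 0, seed = 93)
  sc <- generateSubject(cfgc, "A", 7L)
  load <- decm:::.blob_loadings(cfgc)[, 1]
  strong <- which(load > 0.6)
  ts <- seriesValues(extractTimeseries(sc$volume, synthMask(cfgc)))
  cc <- cor(t(ts[strong, ]))
  expect_gt(min(cc), 0.9)
})

test_that("changing only the group-effect knob changes only coupling", {
  cfg_lo <- small_cfg(94, effect = 1L)
  cfg_hi <- synthConfig(grid = c(10L, 10L, 6L), nTime = 40L, nNetworks = 2L,
                        blobWidth = 1.5, nPerGroup = 8L, effectNetwork = 1L,
                        couplingSd = c(0.15, 0.3) * 2, seed = 94L)
  a <- generateSubject(cfg_lo, "B", 555L)
  b <- generateSubject(cfg_hi, "B", 555L)
  expect_identical(a$truth$latent, b$truth$latent)
  # drift shapes identical up to the scale applied (before clamping)
  sa <- a$truth$coupling[1, ]; sb <- b$truth$coupling[1, ]
  free <- sa > 0.02 & sa < 0.98 & sb > 0.02 & sb < 0.98
  expect_equal((sb[free] - 0.5) / 0.6, (sa[free] - 0.5) / 0.3,
               tolerance = 1e-12)
  expect_false(identical(imgData(a$volume), imgData(b$volume)))
})

test_that("cohorts are balanced, seeded and carry a usable design table", {
  cfg <- small_cfg(95, nPerGroup = 2L)
  co <- generateCohort(cfg)
  expect_length(co$subjects, 4)
  expect_equal(nrow(co$design), 4)
  expect_equal(table(co$design$group), table(rep(c("A", "B"), each = 2)),
               ignore_attr = TRUE)
  expect_setequal(names(co$design),
                  c("subject", "group", "age", "scan_length"))
  co2 <- generateCohort(cfg)
  expect_identical(imgData(co$subjects[[3]]$volume),
                   imgData(co2$subjects[[3]]$volume))
  expect_identical(co$design, co2$design)
  # optional variable scan lengths exercise the covariate
  cov <- generateCohort(cfg, scanLengths = c(40L, 50L))
  expect_true(all(cov$design$scan_length %in% c(40L, 50L)))
  expect_equal(dim(cov$subjects[[1]]$volume)[4],
               cov$design$scan_length[1])
})

test_that("higher coupling variability raises measured network EC variability", {
  cfg <- small_cfg(96, effect = 1L, nPerGroup = 3L)
  co <- generateCohort(cfg)
  sel <- seriesValues(co$templates)[, 1] > 3
  amp <- vapply(co$subjects, function(s) {
    cs <- slidingWindowEcm(extractTimeseries(s$volume, co$mask), 20)
    sd(colMeans(seriesValues(cs)[sel, ]))
  }, numeric(1))
  grp <- co$design$group
  expect_gt(mean(amp[grp == "B"]), mean(amp[grp == "A"]))
})
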