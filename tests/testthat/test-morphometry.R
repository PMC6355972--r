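# Thresholding, segmentation and the volume / area / sphericity
# measurements, checked against analytic oracles.

test_that("Otsu threshold matches the exhaustive within-class-variance scan", {
  set.seed(1)
  v <- c(rnorm(900, 10, 1), rnorm(100, 100, 5))  # two-level, 90/10 mix
  arr <- array(pmax(v, 0), dim = c(10, 10, 10))
  thr <- selectThreshold(arr, "otsu")
  oracle <- otsuExhaustive(as.numeric(arr))
  binWidth <- diff(range(arr)) / 256
  expect_lt(abs(as.numeric(thr) - oracle), 2 * binWidth)
  expect_gt(as.numeric(thr), 10)
  expect_lt(as.numeric(thr), 100)
})

test_that("otsu_plus_k_sd shifts the baseline by k global SDs", {
  ph <- makeSphereStack(5, noiseSd = 5, seed = 2)
  base <- selectThreshold(ph$stack, "otsu")
  k0 <- selectThreshold(ph$stack, "otsu_plus_k_sd", k = 0)
  k1 <- selectThreshold(ph$stack, "otsu_plus_k_sd", k = 1)
  expect_equal(as.numeric(k0), as.numeric(base))
  expect_equal(as.numeric(k1),
               as.numeric(base) + sd(channelData(ph$stack, 1)))
  expect_gte(as.numeric(k1), as.numeric(base))
})

test_that("constant images reject Otsu; fixed thresholds pass through", {
  expect_error(selectThreshold(array(5, dim = c(4, 4, 4)), "otsu"),
               "constant")
  thr <- selectThreshold(NULL, "fixed", value = 42)
  expect_identical(as.numeric(thr), 42)
  expect_identical(attr(thr, "method"), "fixed")
})

test_that("volume is voxel count times physical voxel volume", {
  arr <- array(10, dim = c(14, 14, 14))
  arr[3:12, 3:12, 3:12] <- 100       # 1000 voxels
  m <- segmentCells(arr, 50, minVolumeUm3 = 1,
                    spacingUm = c(0.2, 0.2, 0.4), detectDoublets = FALSE)
  expect_equal(measureVolume(m, 1), 1000 * 0.2 * 0.2 * 0.4)
  expect_error(measureVolume(m, 99), "absent")
})

test_that("digitized spheres recover analytic volume within 2% and area within 3%", {
  for (r in c(2.5, 5)) {
    ph <- makeSphereStack(r, spacingUm = c(0.2, 0.2, 0.2))
    m <- segmentCells(ph$stack, selectThreshold(ph$stack, "otsu"),
                      detectDoublets = FALSE, minVolumeUm3 = 10)
    v <- measureVolume(m, 1)
    a <- measureSurfaceArea(m, 1)
    expect_lt(abs(v / (4 / 3 * pi * r^3) - 1), 0.02)
    expect_lt(abs(a / (4 * pi * r^2) - 1), 0.03)
  }
})

test_that("a 10-um cube's mesh area is within 5% of 600 um^2", {
  arr <- array(10, dim = c(70, 70, 70))
  arr[11:60, 11:60, 11:60] <- 100    # 50 voxels * 0.2 um = 10 um sides
  m <- segmentCells(arr, 50, spacingUm = c(0.2, 0.2, 0.2),
                    detectDoublets = FALSE)
  expect_equal(measureVolume(m, 1), 1000)
  expect_lt(abs(measureSurfaceArea(m, 1) / 600 - 1), 0.05)
})

test_that("sphericity formula hits its closed-form anchors and rejects bad input", {
  expect_equal(sphericity(4 / 3 * pi * 125, 4 * pi * 25), 1, tolerance = 1e-12)
  expect_equal(sphericity(1, 6), (pi / 6)^(1 / 3), tolerance = 1e-12)
  expect_error(sphericity(0, 6), "positive")
  expect_error(sphericity(1, -1), "positive")
})

test_that("measured sphericity decreases with ellipsoid aspect, tracking the closed form", {
  aspects <- c(2, 5)
  vals <- vapply(aspects, function(asp) {
    ph <- makeEllipsoidStack(c(2.5, 2.5, 2.5 * asp),
                             spacingUm = c(0.4, 0.4, 0.4))
    m <- segmentCells(ph$stack, selectThreshold(ph$stack, "otsu"),
                      detectDoublets = FALSE, minVolumeUm3 = 10)
    meas <- sphericity(measureVolume(m, 1), measureSurfaceArea(m, 1))
    truth <- truthValues(ph$truth)$sphericity
    expect_lt(abs(meas - truth), 0.05)
    # independent closed-form oracle for the prolate case
    vol <- 4 / 3 * pi * 2.5^2 * 2.5 * asp
    expect_equal(truth, pi^(1 / 3) * (6 * vol)^(2 / 3) /
                   prolateArea(2.5, 2.5 * asp), tolerance = 1e-9)
    meas
  }, numeric(1))
  expect_lt(vals[2], vals[1])
  expect_lt(vals[1], 1)
})

test_that("volumes are additive over disjoint labels and scale as r^3", {
  two <- makeTwoSphereStack(4, gapUm = 5, spacingUm = c(0.25, 0.25, 0.25))
  m <- segmentCells(two$stack, selectThreshold(two$stack, "otsu"),
                    detectDoublets = FALSE)
  qc <- qcFlags(m)
  expect_identical(nrow(qc), 2L)
  v1 <- measureVolume(m, 1); v2 <- measureVolume(m, 2)
  expect_equal(v1 + v2, sum(qc$volume_um3), tolerance = 1e-9)
  expect_equal(v1, v2, tolerance = 0.01)

  vr <- vapply(c(3, 6), function(r) {
    ph <- makeSphereStack(r, spacingUm = c(0.25, 0.25, 0.25))
    mm <- segmentCells(ph$stack, selectThreshold(ph$stack, "otsu"),
                       detectDoublets = FALSE, minVolumeUm3 = 10)
    measureVolume(mm, 1)
  }, numeric(1))
  expect_equal(vr[2] / vr[1], 8, tolerance = 0.02)
})

test_that("anisotropic and isotropic sampling of one sphere agree within 3%", {
  iso <- makeSphereStack(5, spacingUm = c(0.2, 0.2, 0.2))
  ani <- makeSphereStack(5, spacingUm = c(0.2, 0.2, 0.4))
  vols <- vapply(list(iso, ani), function(ph) {
    m <- segmentCells(ph$stack, selectThreshold(ph$stack, "otsu"),
                      detectDoublets = FALSE)
    measureVolume(m, 1)
  }, numeric(1))
  expect_lt(abs(vols[1] / vols[2] - 1), 0.03)
})

test_that("QC flags: border contact, separation, merged contact pair", {
  # sphere pushed against the stack border
  ph <- makeSphereStack(5, centerUm = c(4, 7, 7))
  m <- segmentCells(ph$stack, selectThreshold(ph$stack, "otsu"),
                    detectDoublets = FALSE)
  expect_true(qcFlags(m)$touches_border[1])

  sep <- makeTwoSphereStack(5, gapUm = 4)
  ms <- segmentCells(sep$stack, selectThreshold(sep$stack, "otsu"))
  expect_identical(nrow(qcFlags(ms)), 2L)
  expect_false(any(qcFlags(ms)$touches_other_cell))

  touch <- makeTwoSphereStack(5, gapUm = -0.4)
  mt <- segmentCells(touch$stack, selectThreshold(touch$stack, "otsu"))
  expect_identical(nrow(qcFlags(mt)), 1L)
  expect_true(qcFlags(mt)$touches_other_cell[1])

  # a single sphere and a protrusion must not be mistaken for doublets
  lone <- makeSphereStack(5)
  ml <- segmentCells(lone$stack, selectThreshold(lone$stack, "otsu"))
  expect_false(qcFlags(ml)$touches_other_cell[1])
  prot <- makeProtrusionStack(5, 10, 1)
  mp <- segmentCells(prot$stack, selectThreshold(prot$stack, "otsu"))
  expect_false(qcFlags(mp)$touches_other_cell[1])
})

test_that("empty foreground yields zero labels with a warning, not an error", {
  arr <- array(5, dim = c(8, 8, 8)); arr[1] <- 6
  expect_warning(m <- segmentCells(arr, 6, spacingUm = 0.2), "empty")
  expect_identical(nrow(qcFlags(m)), 0L)
  expect_identical(max(maskLabels(m)), 0L)
})

test_that("sub-minimum components are removed as debris", {
  arr <- array(10, dim = c(40, 40, 40))
  arr[5:30, 5:30, 5:30] <- 100   # big block
  arr[35:36, 35:36, 35:36] <- 100  # 8-voxel speck
  m <- segmentCells(arr, 50, minVolumeUm3 = 65, spacingUm = c(0.5, 0.5, 0.5),
                    detectDoublets = FALSE)
  expect_identical(nrow(qcFlags(m)), 1L)
})

test_that("volume is non-increasing in the threshold adjustment k", {
  ph <- makeSphereStack(5, noiseSd = 6, seed = 4)
  tab <- thresholdSensitivity(ph$stack, kList = c(0, 0.5, 1, 2))
  expect_true(all(diff(tab$largest_volume_um3) <= 1e-9))
  expect_true(all(diff(tab$total_volume_um3) <= 1e-9))
  expect_true(all(diff(tab$threshold) > 0))
  expect_equal(tab$volume_rel[1], 1)

  # noiseless two-level image: any threshold between the modes gives the
  # same foreground, so volumes are equal while the threshold stays there
  ph0 <- makeSphereStack(5)
  tab0 <- thresholdSensitivity(ph0$stack, kList = c(0, 0.1))
  expect_equal(tab0$largest_volume_um3[1], tab0$largest_volume_um3[2])
})

test_that("bead calibration: small zero-noise bias, offset invariance, noise raises CV", {
  measureBead <- function(r, noiseSd, seed, offset = 0) {
    ph <- makeSphereStack(r, spacingUm = c(0.3, 0.3, 0.3),
                          intensityFg = 100 + offset, intensityBg = 10 + offset,
                          noiseSd = noiseSd, seed = seed)
    m <- segmentCells(ph$stack, selectThreshold(ph$stack, "otsu"),
                      detectDoublets = FALSE, minVolumeUm3 = 10)
    measureVolume(m, 1)
  }
  truth <- 4 / 3 * pi * 4^3
  clean <- vapply(1:3, function(s) measureBead(4, 0, s), numeric(1))
  cal <- beadCalibration(data.frame(nominal = "8um", true_volume_um3 = truth,
                                    measured_volume_um3 = clean))
  expect_lt(abs(cal$bias_percent), 2)

  # constant intensity offset must not change the measurement
  expect_equal(measureBead(4, 0, 1, offset = 40), measureBead(4, 0, 1))

  noisy <- function(sd) vapply(1:6, function(s) measureBead(4, sd, s),
                               numeric(1))
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(noisy(20)), cv(noisy(2)))
})
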