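# Synthetic phantom generators: analytic truths, determinism, and
# rejection of unresolvable or inconsistent geometry.

test_that("sphere phantom truth matches the closed-form volume and area", {
  cases <- list(
    list(r = 5, vol = 4 / 3 * pi * 125, area = 4 * pi * 25),
    list(r = 7.5, vol = 1767.146, area = 4 * pi * 7.5^2) # 15-um bead analog
  )
  for (cs in cases) {
    ph <- makeSphereStack(cs$r, spacingUm = c(0.2, 0.2, 0.2))
    tv <- truthValues(ph$truth)
    expect_equal(tv$volume_um3, cs$vol, tolerance = 1e-5)
    expect_equal(tv$area_um2, cs$area, tolerance = 1e-12)
    expect_equal(tv$sphericity, 1)
  }
})

test_that("generators are byte-identical under a fixed seed", {
  a <- makeSphereStack(5, noiseSd = 8, seed = 42)
  b <- makeSphereStack(5, noiseSd = 8, seed = 42)
  expect_identical(stackData(a$stack), stackData(b$stack))
  c <- makeSphereStack(5, noiseSd = 8, seed = 43)
  expect_false(identical(stackData(a$stack), stackData(c$stack)))

  t1 <- makePopulationTable(seed = 7)
  t2 <- makePopulationTable(seed = 7)
  expect_identical(t1$table, t2$table)

  r1 <- makeRelaxationTrace("maxwell", noiseSd = 0.05, seed = 5)
  r2 <- makeRelaxationTrace("maxwell", noiseSd = 0.05, seed = 5)
  expect_identical(traceData(r1$trace), traceData(r2$trace))
})

test_that("unresolvable or inconsistent phantom geometry is rejected", {
  expect_error(makeSphereStack(0.5, spacingUm = c(0.4, 0.4, 0.4)),
               "resolvable")
  expect_error(makeSphereStack(5, intensityFg = 10, intensityBg = 20),
               "foreground > background")
  expect_error(makeProtrusionStack(5, 10, armRadiusUm = 6), "smaller")
  expect_error(makeNCCell(cellRadiusUm = 5, nucleusRadiusUm = 5),
               "strictly smaller")
  expect_error(makeAccumulationPhantom(marginUm = 20), "30 um")
  expect_error(makeRelaxationTrace("sls", plateauFraction = 1.2), "plateau")
})

test_that("protrusion truth volume is the analytic union; L = 0 degenerates", {
  ph <- makeProtrusionStack(5, 10, 1)
  expected <- 4 / 3 * pi * 125 + pi * 10 + 2 / 3 * pi + pi / 20
  expect_equal(truthValues(ph$truth)$volume_um3, expected, tolerance = 1e-12)

  ph0 <- makeProtrusionStack(5, 0, 1)
  expect_equal(truthValues(ph0$truth)$volume_um3, 4 / 3 * pi * 125,
               tolerance = 1e-12)
  expect_identical(phantomKind(ph0$truth), "protrusion")
})

test_that("digitized truth volume converges to analytic truth with spacing", {
  voxCountVolume <- function(sp) {
    ph <- makeSphereStack(5, spacingUm = rep(sp, 3))
    arr <- channelData(ph$stack, 1)
    sum(arr > 50) * sp^3
  }
  true <- 4 / 3 * pi * 125
  errCoarse <- abs(voxCountVolume(0.5) / true - 1)
  errFine <- abs(voxCountVolume(0.2) / true - 1)
  expect_lt(errFine, 0.02)     # < 2% at 0.2 um for r >= 5 um
  expect_lt(errFine, errCoarse + 1e-3)
})

test_that("nc-cell truth ratio follows the prescribed intensities", {
  expect_equal(truthValues(makeNCCell(10, 5, 100, 200)$truth)$nc_ratio, 2)
  expect_equal(truthValues(makeNCCell(10, 5, 150, 150)$truth)$nc_ratio, 1)
})

test_that("relaxation trace truths follow the model half-time formulas", {
  mx <- makeRelaxationTrace("maxwell", tauS = 100)
  expect_equal(truthValues(mx$truth)$tau_half_s, 100 * log(2),
               tolerance = 1e-12)
  sls_lo <- makeRelaxationTrace("sls", tauS = 50, plateauFraction = 0.2)
  expect_equal(truthValues(sls_lo$truth)$tau_half_s,
               50 * log(0.8 / 0.3), tolerance = 1e-12)
  sls_hi <- makeRelaxationTrace("sls", plateauFraction = 0.6)
  expect_true(is.na(truthValues(sls_hi$truth)$tau_half_s))
  el <- makeRelaxationTrace("elastic")
  expect_true(is.na(truthValues(el$truth)$tau_half_s))
  # elastic hold stress is constant
  td <- traceData(el$trace)
  expect_equal(var(td$stress_kPa[td$phase == "hold"]), 0)
})

test_that("population phantom honours flat and monotone links", {
  # flat link: k = 0 makes positivity probability a/100 independent of volume
  flat <- makePopulationTable(nCellsPerCondition = 250, linkA = 50,
                              linkK = 0, seed = 11)
  frac <- mean(flat$table$alp_positive)
  n <- nrow(flat$table)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))

  mono <- makePopulationTable(seed = 12)
  sp <- spearmanTrend(mono$table$volume_um3, mono$table$alp_positive)
  expect_gt(sp$rho, 0)
})

test_that("calcium phantom flags the zero-denominator degenerate case", {
  bad <- makeCalciumPhantom(2, furaredLevel = 0)
  expect_false(truthValues(bad$truth)$valid)
  expect_true(is.na(truthValues(bad$truth)$calcium_ratio))
  ok <- makeCalciumPhantom(2)
  expect_true(truthValues(ok$truth)$valid)
})

test_that("ellipsoid truth area uses the exact spheroid formula", {
  ph <- makeEllipsoidStack(c(2.5, 2.5, 12.5), spacingUm = c(0.5, 0.5, 0.5))
  tv <- truthValues(ph$truth)
  expect_false(tv$area_approximate)
  expect_equal(tv$area_um2, prolateArea(2.5, 12.5), tolerance = 1e-9)
})
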