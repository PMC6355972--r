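# Nuclear:cytoplasmic localization: compartment masks, ratio recovery,
# invariances, 2D/3D agreement.

test_that("compartment masks recover concentric-disk geometry", {
  ph <- makeNCCell(10, 5, 100, 200, "2D", noiseSd = 0)
  dapi <- channelData(ph$stack, "dapi")
  phall <- channelData(ph$stack, "phalloidin")
  cm <- compartmentMasks(dapi, phall)
  sp <- spacingUm(ph$stack)
  expect_equal(sum(cm$nucleus) * sp["y"] * sp["x"], pi * 25,
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(sum(cm$cytoplasm) * sp["y"] * sp["x"], pi * (100 - 25),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_false(any(cm$nucleus & cm$cytoplasm))
  expect_false(cm$multi_nucleus)
})

test_that("nuclear mask is clipped to the cell; constant DAPI errors", {
  dapi <- matrix(10, 40, 40); dapi[5:22, 5:22] <- 200  # nucleus overshoots
  phall <- matrix(10, 40, 40); phall[15:30, 15:30] <- 150
  cm <- compartmentMasks(dapi, phall)
  expect_true(all(which(cm$nucleus) %in% which(phall > 100)))
  expect_error(compartmentMasks(matrix(7, 20, 20), phall[1:20, 1:20]),
               "constant")
})

test_that("N:C ratio hits exact values on noiseless phantoms", {
  ph <- makeNCCell(10, 5, 100, 200, "2D", noiseSd = 0)
  rec <- ncRatioStack(ph$stack, "2D")
  expect_equal(rec$nc_ratio, 2, tolerance = 1e-9)
  uni <- makeNCCell(10, 5, 150, 150, "2D", noiseSd = 0)
  expect_equal(ncRatioStack(uni$stack, "2D")$nc_ratio, 1, tolerance = 1e-9)
})

test_that("mean measured ratio is within 5% of truth over noisy phantoms", {
  est <- vapply(1:50, function(s) {
    ph <- makeNCCell(8, 4, 100, 150, "2D", seed = s)
    ncRatioStack(ph$stack, "2D", cellId = paste0("c", s))$nc_ratio
  }, numeric(1))
  expect_lt(abs(mean(est) / 1.5 - 1), 0.05)
})

test_that("ratio is invariant to protein-channel scaling and voxel spacing", {
  ph <- makeNCCell(10, 5, 100, 200, "2D", seed = 9)
  dapi <- channelData(ph$stack, "dapi")
  phall <- channelData(ph$stack, "phalloidin")
  prot <- channelData(ph$stack, "protein")
  cm <- compartmentMasks(dapi, phall)
  r1 <- ncRatio(prot, cm$nucleus, cm$cytoplasm)$nc_ratio
  r2 <- ncRatio(prot * 7.3, cm$nucleus, cm$cytoplasm)$nc_ratio
  expect_equal(r1, r2, tolerance = 1e-12)
  # spacing never enters the ratio: same voxels, different metadata
  expect_identical(ncRatioStack(ph$stack, "2D")$nc_ratio,
                   ncRatioStack(ImageStack(stackData(ph$stack), c(1, 2, 3),
                                           channelNames(ph$stack)),
                                "2D")$nc_ratio)
})

test_that("3D ratio matches truth; mid-plane 2D agrees with 3D", {
  ph <- makeNCCell(8, 4, 100, 200, "3D", spacingUm = c(0.25, 0.25, 0.5),
                   noiseSd = 0)
  r3 <- ncRatioStack(ph$stack, "3D")
  expect_equal(r3$nc_ratio, 2, tolerance = 1e-9)
  r2 <- ncRatioStack(ph$stack, "2D")
  expect_lt(abs(r2$nc_ratio / r3$nc_ratio - 1), 0.05)
})

test_that("paired 2D/3D records: identical pairs, simulated concordance, n guard", {
  same <- data.frame(cell_id = paste0("c", 1:5), nc_ratio = c(1, 1.5, 2, 2.5, 3))
  res <- compare2D3D(same, same)
  expect_equal(res$correlation, 1)
  expect_equal(res$mean_difference, 0)

  # shared truth + independent 5% measurement noise, n = 50
  set.seed(21)
  truth <- runif(50, 0.8, 3.5)
  r2d <- data.frame(cell_id = paste0("c", 1:50),
                    nc_ratio = truth * (1 + rnorm(50, sd = 0.05)))
  r3d <- data.frame(cell_id = paste0("c", 1:50),
                    nc_ratio = truth * (1 + rnorm(50, sd = 0.05)))
  res2 <- compare2D3D(r2d, r3d)
  expect_gt(res2$correlation, 0.9)
  expect_identical(res2$n, 50L)

  expect_error(compare2D3D(same[1:2, ], same[1:2, ]), "at least 3")
})
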