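# Round-trips for stacks, traces and tables; spacing metadata handling.

test_that("stack write/read round-trips data and metadata", {
  ph <- makeSphereStack(5, spacingUm = c(0.25, 0.2, 0.4), noiseSd = 4,
                        seed = 3)
  f <- withr::local_tempfile(fileext = ".tif")
  writeStack(ph$stack, f)
  back <- readStack(f)
  # 32-bit float storage: exact to single precision
  expect_equal(stackData(back), stackData(ph$stack), tolerance = 1e-6)
  expect_identical(spacingUm(back), spacingUm(ph$stack))
  expect_identical(channelNames(back), channelNames(ph$stack))
})

test_that("multi-channel stacks keep channel identity through files", {
  ph <- makeNCCell(8, 4, 100, 200, "2D", seed = 2)
  f <- withr::local_tempfile(fileext = ".tif")
  writeStack(ph$stack, f)
  back <- readStack(f)
  expect_identical(channelNames(back), c("dapi", "phalloidin", "protein"))
  expect_equal(channelData(back, "protein"),
               channelData(ph$stack, "protein"), tolerance = 1e-6)
})

test_that("spacing resolution: override > sidecar; absent spacing errors", {
  ph <- makeSphereStack(5)
  f <- withr::local_tempfile(fileext = ".tif")
  writeStack(ph$stack, f)
  over <- readStack(f, spacing = c(1, 1, 2))
  expect_identical(unname(spacingUm(over)), c(1, 1, 2))
  # remove the sidecar: plain TIFF with no spacing must error
  file.remove(paste0(f, ".json"))
  expect_error(readStack(f), "spacing")
  expect_silent(readStack(f, spacing = 0.2))
})

test_that("OME-XML PhysicalSize attributes are parsed into spacing", {
  desc <- paste0(
    '<?xml version="1.0"?><OME xmlns="http://www.openmicroscopy.org/',
    'Schemas/OME/2016-06"><Image><Pixels PhysicalSizeX="0.2" ',
    'PhysicalSizeY="0.25" PhysicalSizeZ="0.4"/></Image></OME>')
  sp <- parseOmeSpacing(desc)
  expect_identical(sp, c(y = 0.25, x = 0.2, z = 0.4))
  expect_null(parseOmeSpacing("not xml at all"))
  expect_null(parseOmeSpacing("<OME><Image/></OME>"))
})

test_that("trace files round-trip and reject non-monotone time", {
  tr <- makeRelaxationTrace("maxwell", tauS = 50, durationS = 200)$trace
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr, f)
  back <- readTrace(f)
  expect_equal(traceData(back)$stress_kPa, traceData(tr)$stress_kPa,
               tolerance = 1e-9)
  expect_identical(traceData(back)$phase, traceData(tr)$phase)

  # two-column, whitespace-separated, no header
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%g %g", 0:9, exp(-(0:9) / 5)), f2)
  tw <- readTrace(f2)
  expect_identical(unique(traceData(tw)$phase), "hold")
  expect_equal(traceData(tw)$time_s, as.numeric(0:9))

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,stress", "0,1", "2,0.9", "1,0.8"), f3)
  expect_error(readTrace(f3), "strictly increasing")
})

test_that("tables round-trip; tidy-table invariants are enforced", {
  df <- data.frame(cell_id = c("a", "b"), volume_um3 = c(523.599, 1767.15),
                   condition = "fast")
  f <- withr::local_tempfile(fileext = ".csv")
  writeTable(df, f)
  back <- readTable(f)
  expect_equal(back$volume_um3, df$volume_um3, tolerance = 1e-6)

  tidy <- asTidyTable(df)
  expect_true(all(c("cell_id", "measurement", "value", "units") %in%
                    names(tidy)))
  expect_identical(tidy$units[tidy$measurement == "volume_um3"][1], "um^3")
  dup <- rbind(tidy, tidy[1, ])
  expect_error(writeTable(dup, f), "duplicate")
  bad <- tidy; bad$units <- ""
  expect_error(writeTable(bad, f), "units")
})
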