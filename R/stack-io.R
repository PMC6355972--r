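# TIFF / CSV / trace I/O. All format handling lives here.
#
# Stacks are written as multi-page 32-bit float TIFF. TIFF float
# samples are stored in [0, 1], so intensities are divided by a scale
# factor recorded in a JSON sidecar (<file>.json) together with voxel
# spacing, channel names and page layout. On read, spacing is resolved
# in priority order: explicit override > sidecar > OME-XML ImageDescription
# (files produced by other tools) > error. There is deliberately no
# default spacing.

#' Write an ImageStack to multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2,
#' ...). Intensities are stored as 32-bit float scaled into `[0, 1]`;
#' the scale, spacing, channel names and metadata go to `<path>.json`.
#' Round-trips are exact to single precision.
#'
#' @param stack an [ImageStack-class].
#' @param path output file (`.tif`).
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  d <- stackData(stack)
  dm <- dim(d)
  scale <- max(d, 1e-12)
  pages <- vector("list", dm[3] * dm[4])
  i <- 0L
  for (ch in seq_len(dm[4]))
    for (z in seq_len(dm[3])) {
      i <- i + 1L
      pages[[i]] <- matrix(d[, , z, ch] / scale, nrow = dm[1])
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(
    format = "cellvol3d-stack",
    dims = as.integer(dm),
    spacing_um = as.list(spacingUm(stack)),
    channel_names = as.list(channelNames(stack)),
    intensity_scale = scale,
    page_order = "channel_major",
    meta = stackMeta(stack)
  )
  jsonlite::write_json(sidecar, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.sidecarPath <- function(path) paste0(path, ".json")

#' Read an image stack from TIFF
#'
#' Spacing is taken from, in order: the `spacing` argument; the JSON
#' sidecar written by [writeStack()]; OME-XML `PhysicalSizeX/Y/Z`
#' attributes in the TIFF ImageDescription. A plain TIFF with none of
#' these is an error -- never a silent default.
#'
#' @param path TIFF file.
#' @param spacing optional spacing override, micrometres: scalar or
#'   length-3 `(y, x, z)`.
#' @param channelNames optional channel-name override. Without sidecar
#'   information all pages are treated as z-planes of one channel.
#' @return An [ImageStack-class]; intensities as stored (bit-exact at
#'   32-bit float precision).
#' @export
readStack <- function(path, spacing = NULL, channelNames = NULL) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)

  sidecar <- NULL
  if (file.exists(.sidecarPath(path)))
    sidecar <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)

  desc <- attr(pages[[1]], "description")
  omeSpacing <- if (!is.null(desc) && nzchar(desc)) parseOmeSpacing(desc) else NULL

  if (!is.null(spacing)) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    spacing <- stats::setNames(as.numeric(spacing), c("y", "x", "z"))
  } else if (!is.null(sidecar)) {
    spacing <- stats::setNames(
      as.numeric(unlist(sidecar$spacing_um[c("y", "x", "z")])), c("y", "x", "z"))
  } else if (!is.null(omeSpacing)) {
    spacing <- omeSpacing
  } else {
    stop("no voxel spacing for '", path, "': supply spacing=, or provide a ",
         ".json sidecar or OME ImageDescription. Refusing to guess.")
  }

  np <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  if (!is.null(sidecar)) {
    dm <- as.integer(sidecar$dims)
    scale <- as.numeric(sidecar$intensity_scale)
    cn <- as.character(unlist(sidecar$channel_names))
    meta <- if (is.null(sidecar$meta)) list() else as.list(sidecar$meta)
  } else {
    dm <- c(ny, nx, np, 1L)
    scale <- 1
    cn <- if (is.null(channelNames)) "ch1" else channelNames
    meta <- list()
  }
  if (!is.null(channelNames)) cn <- channelNames
  arr <- array(0, dim = dm)
  i <- 0L
  for (ch in seq_len(dm[4]))
    for (z in seq_len(dm[3])) {
      i <- i + 1L
      arr[, , z, ch] <- pages[[i]] * scale
    }
  ImageStack(arr, spacing, cn, meta)
}

#' Parse voxel spacing from an OME-XML ImageDescription
#'
#' Extracts `PhysicalSizeX/Y/Z` (micrometre units assumed, the OME
#' default) from the first `Pixels` element. Returns `NULL` when the
#' string is not OME-XML or carries no sizes; a missing `PhysicalSizeZ`
#' falls back to 1 um with a warning only if X/Y are present.
#'
#' @param desc ImageDescription string.
#' @return Named spacing vector `c(y=, x=, z=)` or `NULL`.
#' @export
parseOmeSpacing <- function(desc) {
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  gx <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  sx <- gx("PhysicalSizeX"); sy <- gx("PhysicalSizeY"); sz <- gx("PhysicalSizeZ")
  if (is.na(sx) || is.na(sy)) return(NULL)
  if (is.na(sz)) {
    warning("OME description lacks PhysicalSizeZ; using 1 um")
    sz <- 1
  }
  c(y = sy, x = sx, z = sz)
}

#' Write a measurement table to CSV
#'
#' Numeric columns are rounded to `sigDigits` significant digits so
#' repeated runs with the same seed are byte-identical. When the table
#' is in tidy long form (`cell_id`, `measurement`, `value`, `units`),
#' duplicate `(cell_id, measurement)` pairs and empty units are
#' rejected.
#'
#' @param records data.frame.
#' @param path output CSV path.
#' @param sigDigits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
writeTable <- function(records, path, sigDigits = 6) {
  stopifnot(is.data.frame(records))
  if (all(c("cell_id", "measurement") %in% names(records))) {
    key <- paste(records$cell_id, records$measurement)
    if (anyDuplicated(key))
      stop("duplicate (cell_id, measurement) pairs in tidy table")
    if ("units" %in% names(records) &&
        any(!nzchar(as.character(records$units))))
      stop("tidy table units must be non-empty")
  }
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], signif, digits = sigDigits)
  utils::write.table(records, path, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Read a measurement table written by [writeTable()]
#' @param path CSV path.
#' @return data.frame.
#' @export
readTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Reshape per-cell records into a tidy long table
#'
#' One row per `(cell_id, measurement)` with explicit units, the
#' exchange format the reporting stage consumes.
#'
#' @param records wide data.frame with a `cell_id` column (and
#'   optionally `condition`); every numeric column becomes a
#'   measurement.
#' @param units named character vector mapping measurement names to
#'   units; unmapped measurements get `"dimensionless"`.
#' @return data.frame with columns `cell_id`, `condition`,
#'   `measurement`, `value`, `units`.
#' @export
asTidyTable <- function(records, units = c(volume_um3 = "um^3",
                                           area_um2 = "um^2",
                                           tau_half_s = "s")) {
  stopifnot("cell_id" %in% names(records))
  cond <- if ("condition" %in% names(records)) records$condition else NA
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  out <- do.call(rbind, lapply(num, function(m) {
    data.frame(cell_id = records$cell_id, condition = cond, measurement = m,
               value = records[[m]],
               units = if (m %in% names(units)) units[[m]] else "dimensionless")
  }))
  rownames(out) <- NULL
  out
}

#' Read a stress trace from delimited text
#'
#' Accepts two columns (time, stress) or three (time, stress, strain),
#' comma-, tab- or whitespace-separated, with or without a header line
#' (detected by non-numeric tokens). With a strain column, samples at
#' `>= 99.9%` of the maximum strain after first reaching it are the
#' hold phase and earlier samples the ramp; without one, the whole
#' trace is treated as a hold at `holdStrain`.
#'
#' @param path delimited text file.
#' @param holdStrain strain fraction assumed for two-column files.
#' @return A [TraceRecord-class].
#' @export
readTrace <- function(path, holdStrain = 0.15) {
  if (!file.exists(path)) stop("cannot read trace: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  tok <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(tok))))
  df <- utils::read.table(path, header = hasHeader, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("trace file needs at least time and stress columns")
  time <- as.numeric(df[[1]]); stress <- as.numeric(df[[2]])
  if (anyNA(time) || anyNA(stress)) stop("non-numeric values in trace file")
  if (any(diff(time) <= 0)) stop("time column must be strictly increasing")
  if (ncol(df) >= 3L) {
    strain <- as.numeric(df[[3]])
    hs <- max(strain)
    atHold <- strain >= 0.999 * hs
    # the sample that first reaches the hold strain closes the ramp;
    # the hold phase starts at the next sample
    firstMax <- which(atHold)[1]
    phase <- ifelse(seq_along(time) > firstMax, "hold", "ramp")
    if (sum(phase == "ramp") < 2L) phase[] <- "hold"
    TraceRecord(time, stress, strain, phase, hs)
  } else {
    TraceRecord(time, stress, holdStrain, rep("hold", length(time)), holdStrain)
  }
}

#' Write a TraceRecord as delimited text
#' @param trace a [TraceRecord-class].
#' @param path output path (CSV with header).
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  df <- traceData(trace)[, c("time_s", "stress_kPa", "strain")]
  utils::write.table(df, path, sep = ",", row.names = FALSE)
  invisible(path)
}
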