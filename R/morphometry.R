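# 3D single-cell morphometry: threshold -> 26-connected segmentation ->
# voxel-count volume, iso-surface area, sphericity.

.asChannelArray <- function(x, channel = 1L) {
  if (is(x, "ImageStack")) return(channelData(x, channel))
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  if (length(dim(x)) == 3L) return(x)
  stop("expected an ImageStack, matrix or 3D array")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select a segmentation threshold
#'
#' `"otsu"` minimizes intra-class intensity variance over the whole
#' stack (the open, automatic analog of a commercial auto-threshold);
#' `"otsu_plus_k_sd"` returns the Otsu value raised by `k` global
#' intensity standard deviations, the adjustment used to probe
#' measurement uncertainty; `"fixed"` passes `value` through.
#'
#' @param x [ImageStack-class], matrix or 3D array.
#' @param method `"otsu"`, `"fixed"` or `"otsu_plus_k_sd"`.
#' @param k SD multiplier for `"otsu_plus_k_sd"`.
#' @param value threshold for `"fixed"`.
#' @param channel channel used when `x` is a multi-channel stack.
#' @param levels histogram bins for the Otsu scan.
#' @return Numeric threshold with attribute `method`.
#' @export
selectThreshold <- function(x, method = c("otsu", "fixed", "otsu_plus_k_sd"),
                            k = 1, value = NULL, channel = 1L, levels = 256L) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value)) stop("method 'fixed' needs value=")
    return(structure(value, method = "fixed"))
  }
  arr <- .asChannelArray(x, channel)
  rng <- range(arr)
  if (diff(rng) == 0)
    stop("constant image: Otsu threshold is undefined")
  thr <- .otsuThreshold(as.numeric(arr), rng, levels)
  if (method == "otsu_plus_k_sd") thr <- thr + k * stats::sd(arr)
  structure(thr, method = method, k = if (method == "otsu_plus_k_sd") k else NULL)
}

# histogram Otsu via EBImage; returns threshold on the intensity scale
.otsuThreshold <- function(v, rng, levels = 256L) {
  img <- EBImage::Image(matrix(v, ncol = 1L))
  as.numeric(EBImage::otsu(img, range = rng, levels = levels))
}

# --- binary morphology on logical 3D arrays (26-neighbourhood) -------------

.shift3 <- function(a, dy, dx, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
  xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[ys, xs, zs] <- a[ys - dy, xs - dx, zs - dz]
  out
}

.offsets26 <- local({
  g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ]
})

.dilate26 <- function(a) {
  out <- a
  for (i in seq_len(nrow(.offsets26)))
    out <- out | .shift3(a, .offsets26$dy[i], .offsets26$dx[i], .offsets26$dz[i])
  out
}

.erode26 <- function(a) !.dilate26(!a)

# --- segmentation ----------------------------------------------------------

#' Segment single cells from a thresholded stack
#'
#' Foreground is the supra-threshold set, holes are filled per z-slice
#' (membrane dyes label the surface more than the interior, while
#' voxel-count volume presumes solid objects), and 26-connected
#' components are labeled (26-connectivity keeps thin protrusions
#' attached). Components smaller than `minVolumeUm3` are discarded as
#' debris. Each retained cell is QC-flagged: `touches_border` when it
#' meets the stack boundary, `touches_other_cell` when another label
#' lies within one voxel of it or when progressively eroding the
#' component (up to `neckErosionVox` steps) splits it at a contact neck
#' into two or more substantial parts (merged near-touching cells).
#' Flagged cells are kept in the output -- filtering happens downstream,
#' auditable, never silently.
#'
#' @param x [ImageStack-class], matrix or 3D array.
#' @param threshold numeric threshold (e.g. from [selectThreshold()]);
#'   must lie within the intensity range.
#' @param minVolumeUm3 minimum component volume retained; the default
#'   65 um^3 is a sphere of about 2.5 um radius, an explicit,
#'   configurable debris cut.
#' @param channel channel used when `x` is a stack.
#' @param spacingUm spacing override when `x` is a bare array.
#' @param fillHoles fill per-slice holes before labeling.
#' @param detectDoublets run the erosion-split doublet check.
#' @param neckErosionVox maximum erosion depth (voxels) for that check.
#' @return A [LabeledMask-class]. Empty foreground gives zero labels
#'   with a warning, not an error.
#' @export
segmentCells <- function(x, threshold, minVolumeUm3 = 65, channel = 1L,
                         spacingUm = NULL, fillHoles = TRUE,
                         detectDoublets = TRUE, neckErosionVox = 6L) {
  arr <- .asChannelArray(x, channel)
  if (is(x, "ImageStack")) {
    sp <- spacingUm(x)
  } else {
    if (is.null(spacingUm)) stop("spacingUm required for bare arrays")
    if (length(spacingUm) == 1L) spacingUm <- rep(spacingUm, 3L)
    sp <- stats::setNames(as.numeric(spacingUm), c("y", "x", "z"))
  }
  if (threshold < min(arr) || threshold > max(arr))
    stop("threshold ", format(threshold), " outside the intensity range [",
         format(min(arr)), ", ", format(max(arr)), "]")
  d <- dim(arr)
  fg <- arr > threshold
  prov <- list(threshold = as.numeric(threshold),
               method = attr(threshold, "method") %||% "fixed",
               connectivity = 26L, min_volume_um3 = minVolumeUm3,
               fill_holes = fillHoles, neck_erosion_vox = neckErosionVox)
  if (!any(fg)) {
    warning("empty foreground: no cells above threshold")
    return(new("LabeledMask", labels = array(0L, dim = d), spacing = sp,
               provenance = prov,
               qc = data.frame(label = integer(), n_voxels = integer(),
                               volume_um3 = numeric(),
                               touches_border = logical(),
                               touches_other_cell = logical())))
  }
  if (fillHoles) {
    filled <- EBImage::fillHull(array(as.integer(fg), dim = d))
    fg <- as.array(filled) > 0
  }
  lab <- cpp_label26(as.logical(fg), as.integer(d))

  voxvol <- prod(sp)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * voxvol >= minVolumeUm3)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  nlab <- length(keep)
  if (nlab == 0L) {
    warning("all components below minVolumeUm3 = ", minVolumeUm3)
    return(new("LabeledMask", labels = array(as.integer(lab), dim = d),
               spacing = sp, provenance = prov,
               qc = data.frame(label = integer(), n_voxels = integer(),
                               volume_um3 = numeric(),
                               touches_border = logical(),
                               touches_other_cell = logical())))
  }

  border <- array(FALSE, dim = d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  if (d[3] > 1L) border[, , c(1, d[3])] <- TRUE

  nvox <- tabulate(lab[lab > 0L], nbins = nlab)
  touchesBorder <- logical(nlab)
  touchesOther <- logical(nlab)
  for (l in seq_len(nlab)) {
    m <- lab == l
    touchesBorder[l] <- any(m & border)
    if (nlab > 1L) {
      dil <- .dilate26(m)
      if (any(lab > 0L & lab != l & dil)) touchesOther[l] <- TRUE
    }
    if (detectDoublets && !touchesOther[l]) {
      # progressive erosion: a merged pair splits at the contact neck
      # while each body still holds a substantial share of the volume
      er <- m
      for (i in seq_len(neckErosionVox)) {
        er <- .erode26(er)
        if (!any(er)) break
        sub <- cpp_label26(er, as.integer(d))
        ss <- tabulate(sub[sub > 0L])
        if (sum(ss >= 0.1 * nvox[l]) >= 2L) {
          touchesOther[l] <- TRUE
          break
        }
      }
    }
  }
  qc <- data.frame(label = seq_len(nlab), n_voxels = nvox,
                   volume_um3 = nvox * voxvol,
                   touches_border = touchesBorder,
                   touches_other_cell = touchesOther)
  new("LabeledMask", labels = array(as.integer(lab), dim = d), spacing = sp,
      provenance = prov, qc = qc)
}

#' Voxel-count volume of one labeled cell
#'
#' Volume is the number of voxels carrying the label times the physical
#' voxel volume `dy dx dz`.
#'
#' @param mask a [LabeledMask-class].
#' @param label integer label (must be present).
#' @return Volume in cubic micrometres.
#' @export
measureVolume <- function(mask, label) {
  stopifnot(is(mask, "LabeledMask"))
  n <- sum(maskLabels(mask) == label)
  if (n == 0L) stop("label ", label, " absent from mask")
  n * prod(spacingUm(mask))
}

#' Iso-surface area of one labeled cell
#'
#' The binary component is lightly smoothed with a separable Gaussian
#' (default 1 voxel SD per axis) and triangulated at the 0.5 level by
#' marching tetrahedra with anisotropic voxel spacing; the area is the
#' triangle-area sum. Smoothing suppresses the voxel staircase, which
#' would otherwise inflate a sphere's area by tens of percent and drag
#' sphericity far below its sphere = 1 anchor. A component thinner than
#' two voxels along some axis is computed with a warning.
#'
#' @param mask a [LabeledMask-class].
#' @param label integer label.
#' @param smoothSigmaVox Gaussian SD per axis, voxels. `0` disables
#'   smoothing.
#' @return Area in square micrometres.
#' @export
measureSurfaceArea <- function(mask, label, smoothSigmaVox = 1) {
  stopifnot(is(mask, "LabeledMask"))
  lab <- maskLabels(mask)
  sel <- lab == label
  if (!any(sel)) stop("label ", label, " absent from mask")
  sp <- spacingUm(mask)

  # crop to bounding box with zero padding wide enough for the kernel
  w <- which(sel, arr.ind = TRUE)
  pad <- as.integer(ceiling(3 * max(smoothSigmaVox)) + 2L)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  thick <- hi - lo + 1L
  if (any(thick < 2L))
    warning("label ", label, " is one voxel thick along an axis; ",
            "surface area is poorly defined")
  d <- thick + 2L * pad
  bin <- array(0, dim = d)
  bin[pad + (w[, 1] - lo[1]) + 1L +
        d[1] * (pad + (w[, 2] - lo[2])) +
        d[1] * d[2] * (pad + (w[, 3] - lo[3]))] <- 1
  field <- if (any(smoothSigmaVox > 0))
    .gaussianSmooth(bin, rep(smoothSigmaVox, length.out = 3)) else bin
  cpp_isosurface_area(as.numeric(field), as.integer(d),
                      as.numeric(sp), 0.5)
}

# separable Gaussian smoothing of a 3D array, replicate-padded edges
.gaussianSmooth <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigmaVox[1]
    if (s > 0 && d[1] > 1L) {
      r <- as.integer(ceiling(3 * s))
      k <- stats::dnorm(-r:r, sd = s); k <- k / sum(k)
      m <- matrix(arr, d[1], prod(d[-1]))
      mp <- m[c(rep(1L, r), seq_len(d[1]), rep(d[1], r)), , drop = FALSE]
      f <- stats::filter(mp, k, sides = 2)
      arr <- array(as.numeric(f[r + seq_len(d[1]), , drop = FALSE]), dim = d)
    }
    arr <- aperm(arr, c(2, 3, 1))
    d <- d[c(2, 3, 1)]
    sigmaVox <- sigmaVox[c(2, 3, 1)]
  }
  arr
}

#' Sphericity index
#'
#' \deqn{\Psi = \frac{\pi^{1/3} (6 V)^{2/3}}{A}}
#' equals 1 for a sphere and tends to 0 for a line. Vectorized.
#'
#' @param volumeUm3 volume(s), cubic micrometres, > 0.
#' @param areaUm2 surface area(s), square micrometres, > 0.
#' @return Dimensionless sphericity.
#' @examples
#' sphericity(4 / 3 * pi * 125, 4 * pi * 25)  # sphere: exactly 1
#' sphericity(1, 6)                           # unit cube: (pi/6)^(1/3)
#' @export
sphericity <- function(volumeUm3, areaUm2) {
  if (any(volumeUm3 <= 0) || any(areaUm2 <= 0))
    stop("sphericity requires positive volume and area")
  pi^(1 / 3) * (6 * volumeUm3)^(2 / 3) / areaUm2
}

#' Measure all cells in a labeled mask
#'
#' One row per label: voxel-count volume, iso-surface area, sphericity,
#' the threshold recorded in the mask provenance and the QC flags.
#'
#' @param mask a [LabeledMask-class].
#' @param smoothSigmaVox passed to [measureSurfaceArea()].
#' @return data.frame of per-cell morphometry records.
#' @export
measureCells <- function(mask, smoothSigmaVox = 1) {
  qc <- qcFlags(mask)
  if (nrow(qc) == 0L)
    return(data.frame(cell_id = character(), label = integer(),
                      volume_um3 = numeric(), area_um2 = numeric(),
                      sphericity = numeric(), threshold_used = numeric(),
                      touches_border = logical(),
                      touches_other_cell = logical()))
  vol <- vapply(qc$label, function(l) measureVolume(mask, l), numeric(1))
  area <- vapply(qc$label, function(l)
    measureSurfaceArea(mask, l, smoothSigmaVox), numeric(1))
  data.frame(cell_id = sprintf("cell%03d", qc$label), label = qc$label,
             volume_um3 = vol, area_um2 = area,
             sphericity = sphericity(vol, area),
             threshold_used = provenance(mask)$threshold,
             touches_border = qc$touches_border,
             touches_other_cell = qc$touches_other_cell)
}

#' Volume sensitivity to the segmentation threshold
#'
#' Re-segments at `otsu + k * SD` for each `k` and reports how measured
#' volume responds. Because supra-threshold sets nest as the threshold
#' rises (and per-slice hole filling preserves nesting), total and
#' largest-cell volume are non-increasing in `k`.
#'
#' @param x [ImageStack-class] or 3D array.
#' @param kList SD multipliers to scan.
#' @param channel,spacingUm,minVolumeUm3 as in [segmentCells()].
#' @return data.frame with one row per `k`: threshold, cell count,
#'   total and largest-component volume, and the volume relative to the
#'   smallest `k`.
#' @export
thresholdSensitivity <- function(x, kList = c(0, 1), channel = 1L,
                                 spacingUm = NULL, minVolumeUm3 = 65) {
  arr <- .asChannelArray(x, channel)
  sp <- if (is(x, "ImageStack")) spacingUm(x) else spacingUm
  base <- selectThreshold(arr, "otsu")
  s <- stats::sd(arr)
  rows <- lapply(sort(kList), function(k) {
    thr <- as.numeric(base) + k * s
    if (thr >= max(arr))
      return(data.frame(k = k, threshold = thr, n_cells = 0L,
                        total_volume_um3 = 0, largest_volume_um3 = 0))
    m <- suppressWarnings(segmentCells(arr, thr, minVolumeUm3 = minVolumeUm3,
                                       spacingUm = sp, detectDoublets = FALSE))
    qc <- qcFlags(m)
    data.frame(k = k, threshold = thr, n_cells = nrow(qc),
               total_volume_um3 = sum(qc$volume_um3),
               largest_volume_um3 = if (nrow(qc)) max(qc$volume_um3) else 0)
  })
  out <- do.call(rbind, rows)
  ref <- out$largest_volume_um3[1]
  out$volume_rel <- if (ref > 0) out$largest_volume_um3 / ref else NA_real_
  out
}

#' Bead-phantom calibration of the volume measurement
#'
#' Compares measured against true volumes of calibration beads, grouped
#' by nominal size: percent bias of the mean and coefficient of
#' variation, the two quantities used to validate the technique.
#'
#' @param df data.frame with columns `nominal`, `true_volume_um3`,
#'   `measured_volume_um3`.
#' @return data.frame per nominal size: `n`, `bias_percent`,
#'   `cv_percent`.
#' @export
beadCalibration <- function(df) {
  stopifnot(all(c("nominal", "true_volume_um3", "measured_volume_um3") %in%
                  names(df)))
  out <- do.call(rbind, lapply(split(df, df$nominal), function(g) {
    data.frame(nominal = g$nominal[1], n = nrow(g),
               bias_percent = 100 * mean(g$measured_volume_um3 /
                                           g$true_volume_um3 - 1),
               cv_percent = 100 * stats::sd(g$measured_volume_um3) /
                 mean(g$measured_volume_um3))
  }))
  rownames(out) <- NULL
  out
}
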