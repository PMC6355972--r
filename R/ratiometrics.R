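# Per-cell ratiometric readouts: Fluo-3 / Fura-red calcium and
# peri-cellular alginate accumulation.

#' Ratiometric calcium readout for one cell
#'
#' Mean Fluo-3 intensity over the cell mask divided by the mean
#' Fura-red intensity over the same mask. This is a relative calcium
#' measure, robust to dye loading, not an absolute concentration. A
#' cell whose Fura-red mean falls below `floorFactor` times the
#' background SD of the Fura-red channel (estimated outside the mask)
#' is flagged invalid rather than silently dropped.
#'
#' @param fluo3,furared matrices or 3D arrays, aligned.
#' @param cellMask logical mask, non-empty.
#' @param cellId record identifier.
#' @param floorFactor denominator validity floor, in background SDs.
#' @return One-row data.frame: `cell_id`, `kind`, `value`,
#'   `fluo3_mean`, `furared_mean`, `n_pixels`, `valid`.
#' @export
calciumRatio <- function(fluo3, furared, cellMask, cellId = "cell",
                         floorFactor = 5) {
  fluo3 <- .asChannelArray(fluo3); furared <- .asChannelArray(furared)
  stopifnot(identical(dim(fluo3), dim(furared)))
  if (!any(cellMask)) stop("empty cell mask for ", cellId)
  fm <- mean(fluo3[cellMask])
  rm_ <- mean(furared[cellMask])
  bgSd <- if (any(!cellMask)) stats::sd(furared[!cellMask]) else 0
  floor_ <- floorFactor * max(bgSd, .Machine$double.eps)
  valid <- rm_ > floor_
  data.frame(cell_id = cellId, kind = "calcium",
             value = if (valid) fm / rm_ else NA_real_,
             fluo3_mean = fm, furared_mean = rm_,
             n_pixels = sum(cellMask), valid = valid)
}

#' Peri-cellular matrix accumulation ratio for one cell
#'
#' Mean matrix (alginate) intensity within 3 um outside the cell
#' border, divided by the background intensity of the gel about 30 um
#' away. Distances are Euclidean in physical units from the cell
#' surface (anisotropic voxel spacing respected). "At 30 um" is
#' operationalized as the 28--32 um shell: a measure-zero contour holds
#' no pixels, so a configurable half-width is required. Pixels inside
#' the target cell, and inside any other cell, are excluded from both
#' regions.
#'
#' @param alginate matrix or 3D array of matrix-channel intensities.
#' @param cellMask logical mask of the target cell.
#' @param spacingUm voxel pitch `(y, x, z)`, micrometres.
#' @param innerBandUm inner band distance range, default `c(0, 3)`.
#' @param backgroundShellUm background shell range, default
#'   `c(28, 32)` (30 um centre, 2 um half-width).
#' @param otherCellsMask optional logical mask of all other cells to
#'   exclude from the background.
#' @param cellId record identifier.
#' @return One-row data.frame: `cell_id`, `kind`, `value`,
#'   `inner_mean`, `background_mean`, `n_inner`, `n_background`, plus
#'   the band definition.
#' @export
accumulationRatio <- function(alginate, cellMask, spacingUm,
                              innerBandUm = c(0, 3),
                              backgroundShellUm = c(28, 32),
                              otherCellsMask = NULL, cellId = "cell") {
  alginate <- .asChannelArray(alginate)
  cellMask <- array(cellMask, dim = dim(alginate))
  if (!any(cellMask)) stop("empty cell mask for ", cellId)
  sp <- stats::setNames(as.numeric(spacingUm), c("y", "x", "z"))
  d <- cpp_edt(as.logical(cellMask), as.integer(dim(alginate)),
               as.numeric(sp))
  outside <- !cellMask
  if (!is.null(otherCellsMask)) outside <- outside & !otherCellsMask
  inner <- outside & d > innerBandUm[1] & d <= innerBandUm[2]
  bg <- outside & d >= backgroundShellUm[1] & d <= backgroundShellUm[2]
  if (!any(bg))
    stop("background shell ", backgroundShellUm[1], "-",
         backgroundShellUm[2], " um is empty for ", cellId,
         " (cell too close to the image border or to neighbours)")
  if (!any(inner))
    stop("inner band is empty for ", cellId)
  im <- mean(alginate[inner]); bm <- mean(alginate[bg])
  data.frame(cell_id = cellId, kind = "accumulation", value = im / bm,
             inner_mean = im, background_mean = bm,
             n_inner = sum(inner), n_background = sum(bg),
             inner_band_lo_um = innerBandUm[1],
             inner_band_hi_um = innerBandUm[2],
             background_lo_um = backgroundShellUm[1],
             background_hi_um = backgroundShellUm[2])
}
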