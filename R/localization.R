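# Nuclear:cytoplasmic localization of a target protein from
# DAPI / phalloidin / protein channels, in 2D or 3D.

#' Nucleus, cell and cytoplasm masks from DAPI and phalloidin
#'
#' The nuclear domain is the Otsu-thresholded DAPI channel and the cell
#' domain the Otsu-thresholded phalloidin channel; the non-nuclear
#' cytoplasm is the cell minus the nucleus, and any nuclear signal
#' outside the cell is clipped to it. When the nuclear mask has several
#' connected components the largest is used and the result is flagged
#' (`multi_nucleus`), assuming one nucleus per cell.
#'
#' @param dapi,phalloidin matrices (2D) or 3D arrays, same dimensions,
#'   both non-constant.
#' @param cellId identifier used in error messages.
#' @return list with logical masks `nucleus`, `cell`, `cytoplasm` and
#'   flag `multi_nucleus`.
#' @export
compartmentMasks <- function(dapi, phalloidin, cellId = "cell") {
  dapi <- .asChannelArray(dapi)
  phalloidin <- .asChannelArray(phalloidin)
  stopifnot(identical(dim(dapi), dim(phalloidin)))
  nuc <- dapi > selectThreshold(dapi, "otsu")
  cell <- phalloidin > selectThreshold(phalloidin, "otsu")
  nuc <- nuc & cell                       # clip nucleus to the cell
  multi <- FALSE
  if (any(nuc)) {
    lab <- cpp_label26(as.logical(nuc), as.integer(dim(nuc)))
    sizes <- tabulate(lab[lab > 0L])
    if (length(sizes) > 1L) {
      multi <- TRUE
      nuc <- lab == which.max(sizes)
    }
  }
  cyto <- cell & !nuc
  if (!any(cyto))
    stop("empty cytoplasm after nuclear subtraction for ", cellId)
  if (!any(nuc))
    stop("empty nuclear domain for ", cellId)
  list(nucleus = nuc, cell = cell, cytoplasm = cyto, multi_nucleus = multi)
}

#' Nuclear:cytoplasmic intensity ratio of a target protein
#'
#' The ratio of the average protein intensity over the nuclear domain
#' to the average over the non-nuclear cytoplasm -- a ratio of
#' compartment means, not a mean of per-pixel ratios, and with no
#' background subtraction by default. The result is invariant to any
#' positive rescaling of the protein channel and independent of voxel
#' spacing.
#'
#' @param protein matrix or 3D array of target-protein intensities.
#' @param nucleusMask,cytoplasmMask logical masks from
#'   [compartmentMasks()].
#' @param cellId record identifier.
#' @param mode `"2D"` or `"3D"` (bookkeeping only).
#' @return One-row data.frame: `cell_id`, `mode`, `nuclear_mean`,
#'   `cytoplasmic_mean`, `nc_ratio`, `nuclear_size`,
#'   `cytoplasmic_size`.
#' @export
ncRatio <- function(protein, nucleusMask, cytoplasmMask,
                    cellId = "cell", mode = "2D") {
  protein <- .asChannelArray(protein)
  if (!any(nucleusMask)) stop("empty nuclear mask for ", cellId)
  if (!any(cytoplasmMask)) stop("empty cytoplasmic mask for ", cellId)
  nm <- mean(protein[nucleusMask])
  cm <- mean(protein[cytoplasmMask])
  if (cm <= 0) stop("zero cytoplasmic mean intensity for ", cellId)
  data.frame(cell_id = cellId, mode = mode, nuclear_mean = nm,
             cytoplasmic_mean = cm, nc_ratio = nm / cm,
             nuclear_size = sum(nucleusMask),
             cytoplasmic_size = sum(cytoplasmMask))
}

#' N:C ratio straight from a 3-channel stack
#'
#' Convenience wrapper: builds volumetric (or planar) compartment masks
#' from the stack's `dapi` and `phalloidin` channels, then measures the
#' `protein` channel. For `mode = "2D"` on a 3D stack the middle
#' z-plane is used by default (`projection = TRUE` uses the mean
#' projection instead).
#'
#' @param stack an [ImageStack-class] with channels `dapi`,
#'   `phalloidin`, `protein`.
#' @param mode `"3D"` (volumetric) or `"2D"`.
#' @param projection for 2D mode, use a mean z-projection rather than
#'   the single mid-plane.
#' @param cellId record identifier.
#' @return One-row data.frame as [ncRatio()].
#' @export
ncRatioStack <- function(stack, mode = c("3D", "2D"), projection = FALSE,
                         cellId = "cell") {
  mode <- match.arg(mode)
  stopifnot(is(stack, "ImageStack"))
  get <- function(ch) channelData(stack, ch)
  dapi <- get("dapi"); phall <- get("phalloidin"); prot <- get("protein")
  if (mode == "2D" && dim(dapi)[3] > 1L) {
    pick <- function(a) {
      if (projection) apply(a, c(1, 2), mean)
      else a[, , ceiling(dim(a)[3] / 2)]
    }
    dapi <- .asChannelArray(pick(dapi))
    phall <- .asChannelArray(pick(phall))
    prot <- .asChannelArray(pick(prot))
  }
  cm <- compartmentMasks(dapi, phall, cellId)
  ncRatio(prot, cm$nucleus, cm$cytoplasm, cellId, mode)
}

#' Agreement between paired 2D and 3D N:C measurements
#'
#' Pearson correlation, paired mean difference and paired t-test
#' p-value between N:C ratios of the same cells measured in 2D and in
#' 3D, the concordance check backing the use of planar analysis.
#'
#' @param records2d,records3d data.frames from [ncRatio()] /
#'   [ncRatioStack()], matched by `cell_id`.
#' @return list: `correlation`, `mean_difference` (2D minus 3D), `p`,
#'   `n`.
#' @export
compare2D3D <- function(records2d, records3d) {
  m <- merge(records2d[, c("cell_id", "nc_ratio")],
             records3d[, c("cell_id", "nc_ratio")],
             by = "cell_id", suffixes = c("_2d", "_3d"))
  if (nrow(m) < 3L)
    stop("need at least 3 paired cells, got ", nrow(m))
  a <- m$nc_ratio_2d; b <- m$nc_ratio_3d
  d <- a - b
  if (stats::sd(d) == 0) {
    p <- 1
  } else {
    p <- stats::t.test(a, b, paired = TRUE)$p.value
  }
  list(correlation = stats::cor(a, b), mean_difference = mean(d),
       p = p, n = nrow(m))
}
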