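#' ImageStack: a multi-channel intensity grid with physical spacing
#'
#' Container for 2D images and 3D confocal stacks. Data are stored as a
#' 4-dimensional array with dimension order `(y, x, z, channel)` and
#' R-native 1-based indexing; a 2D image has a z-extent of 1. Voxel
#' spacing is a named numeric vector `c(y = dy, x = dx, z = dz)` in
#' micrometres, strictly positive. The voxel with index `(i, j, k)` has
#' its centre at physical position `((i - 0.5) dy, (j - 0.5) dx,
#' (k - 0.5) dz)`. This is the single place the coordinate convention is
#' defined; every function in the package follows it.
#'
#' @slot data numeric 4D array `(y, x, z, channel)`, non-negative.
#' @slot spacing named numeric, voxel pitch in micrometres.
#' @slot channelNames character, one name per channel.
#' @slot meta free-form list (acquisition notes, phantom provenance).
#'
#' @name ImageStack-class
#' @aliases ImageStack-class
#' @exportClass ImageStack
setClass("ImageStack",
  slots = c(
    data = "array",
    spacing = "numeric",
    channelNames = "character",
    meta = "list"
  )
)

setValidity("ImageStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 4L)
    return("data must be a 4D array (y, x, z, channel)")
  sp <- object@spacing
  if (length(sp) != 3L || is.null(names(sp)) ||
      !identical(names(sp), c("y", "x", "z")))
    return("spacing must be a named numeric c(y=, x=, z=)")
  if (any(!is.finite(sp)) || any(sp <= 0))
    return("spacing components must be finite and > 0")
  if (length(object@channelNames) != dim(d)[4L])
    return("channelNames length must match the channel axis")
  if (anyNA(d) || min(d) < 0)
    return("intensities must be non-negative and non-missing")
  TRUE
})

#' Construct an ImageStack
#'
#' Accepts a 2D matrix (one-plane, one-channel image), a 3D array
#' (interpreted as `(y, x, z)`, one channel) or a full 4D array
#' `(y, x, z, channel)`.
#'
#' @param data matrix or array of non-negative intensities.
#' @param spacing voxel pitch in micrometres: a single number (isotropic),
#'   or a length-3 vector in `(y, x, z)` order (names optional).
#' @param channelNames character vector naming the channels.
#' @param meta optional list of free-form metadata.
#' @return An [ImageStack-class] object.
#' @examples
#' s <- ImageStack(matrix(0, 8, 8), spacing = 0.2, channelNames = "dapi")
#' spacingUm(s)
#' @export
ImageStack <- function(data, spacing, channelNames = NULL, meta = list()) {
  nd <- length(dim(data))
  if (is.matrix(data)) {
    data <- array(data, dim = c(dim(data), 1L, 1L))
  } else if (nd == 3L) {
    data <- array(data, dim = c(dim(data), 1L))
  } else if (nd != 4L) {
    stop("data must be a matrix or a 3D/4D array")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L) stop("spacing must have length 1 or 3")
  spacing <- stats::setNames(as.numeric(spacing), c("y", "x", "z"))
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(data)[4L]))
  new("ImageStack", data = data, spacing = spacing,
      channelNames = as.character(channelNames), meta = meta)
}

#' LabeledMask: integer cell labels aligned to an ImageStack
#'
#' Labels are 0 for background and contiguous `1..N` for candidate
#' cells. `provenance` records how the mask was produced (threshold
#' value and method, connectivity, minimum size); `qc` holds one row per
#' label with the flags used to audit the paper-style "single cells not
#' in contact" filter.
#'
#' @slot labels integer 3D array `(y, x, z)`.
#' @slot spacing named numeric voxel pitch, micrometres.
#' @slot provenance list; always populated by [segmentCells()].
#' @slot qc data.frame with columns `label`, `n_voxels`,
#'   `touches_border`, `touches_other_cell`.
#'
#' @name LabeledMask-class
#' @exportClass LabeledMask
setClass("LabeledMask",
  slots = c(
    labels = "array",
    spacing = "numeric",
    provenance = "list",
    qc = "data.frame"
  )
)

setValidity("LabeledMask", function(object) {
  l <- object@labels
  if (length(dim(l)) != 3L) return("labels must be a 3D array")
  u <- sort(unique(as.integer(l)))
  u <- u[u != 0L]
  if (length(u) && !identical(u, seq_along(u)))
    return("label set must be contiguous 1..N")
  if (min(l) < 0L) return("labels must be >= 0")
  if (length(object@provenance) == 0L)
    return("provenance must be populated")
  if (length(u) != nrow(object@qc))
    return("qc must have one row per label")
  TRUE
})

#' TraceRecord: a stress-relaxation / stress-strain test
#'
#' Time series from unconfined compression of a hydrogel: a `ramp`
#' phase (strain increasing to the hold strain) followed by a `hold`
#' phase at constant strain during which stress relaxes. Either phase
#' may be absent when a file only covers part of the test.
#'
#' @slot time_s numeric, seconds, non-decreasing; strictly increasing
#'   within each phase.
#' @slot stress_kPa numeric, non-negative.
#' @slot strain unitless strain fraction at each sample.
#' @slot phase character, `"ramp"` or `"hold"` per sample.
#' @slot holdStrain scalar strain fraction held (e.g. 0.15).
#'
#' @name TraceRecord-class
#' @exportClass TraceRecord
setClass("TraceRecord",
  slots = c(
    time_s = "numeric",
    stress_kPa = "numeric",
    strain = "numeric",
    phase = "character",
    holdStrain = "numeric"
  )
)

setValidity("TraceRecord", function(object) {
  n <- length(object@time_s)
  if (length(object@stress_kPa) != n || length(object@strain) != n ||
      length(object@phase) != n)
    return("time, stress, strain and phase must have equal length")
  if (n && is.unsorted(object@time_s))
    return("time must be non-decreasing")
  if (any(!object@phase %in% c("ramp", "hold")))
    return("phase must be 'ramp' or 'hold'")
  if (n && min(object@stress_kPa) < 0)
    return("stress must be non-negative")
  for (ph in unique(object@phase)) {
    tt <- object@time_s[object@phase == ph]
    if (length(tt) < 2L)
      return(sprintf("phase '%s' needs at least 2 samples", ph))
    if (any(diff(tt) <= 0))
      return(sprintf("time must be strictly increasing within phase '%s'", ph))
  }
  TRUE
})

#' Construct a TraceRecord
#'
#' @param time_s sample times, seconds.
#' @param stress_kPa stress, kilopascals.
#' @param strain strain fraction per sample; a scalar is recycled.
#' @param phase `"ramp"`/`"hold"` per sample; by default every sample
#'   is `"hold"`.
#' @param holdStrain the strain held during relaxation (default: the
#'   maximum of `strain`).
#' @return A [TraceRecord-class] object.
#' @export
TraceRecord <- function(time_s, stress_kPa, strain = 0.15,
                        phase = rep("hold", length(time_s)),
                        holdStrain = max(strain)) {
  if (length(strain) == 1L) strain <- rep(strain, length(time_s))
  new("TraceRecord", time_s = as.numeric(time_s),
      stress_kPa = as.numeric(stress_kPa), strain = as.numeric(strain),
      phase = as.character(phase), holdStrain = as.numeric(holdStrain))
}

#' PhantomTruth: exact ground truth of a generated phantom
#'
#' Every generator returns one of these alongside its image or trace, so
#' downstream measurements can be checked against analytic values.
#'
#' @slot kind one of `"sphere"`, `"ellipsoid"`, `"protrusion"`,
#'   `"nc_cell"`, `"accumulation"`, `"calcium"`, `"relaxation"`,
#'   `"population"`.
#' @slot params named list of generator parameters (micrometres,
#'   kilopascals, seconds, dimensionless).
#' @slot seed integer seed used for the stochastic parts.
#' @slot truth named list of expected measurement outputs
#'   (e.g. `volume_um3`, `nc_ratio`, `tau_half_s`).
#'
#' @name PhantomTruth-class
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  slots = c(
    kind = "character",
    params = "list",
    seed = "integer",
    truth = "list"
  )
)

.phantomKinds <- c("sphere", "ellipsoid", "protrusion", "nc_cell",
                   "accumulation", "calcium", "relaxation", "population")

setValidity("PhantomTruth", function(object) {
  if (length(object@kind) != 1L || !object@kind %in% .phantomKinds)
    return(paste("kind must be one of:", paste(.phantomKinds, collapse = ", ")))
  ok <- vapply(object@truth, function(v) {
    !is.numeric(v) || length(v) != 1L || is.na(v) || is.finite(v)
  }, logical(1))
  if (!all(ok)) return("numeric truth entries must be finite (or NA for declared degenerate cases)")
  TRUE
})

PhantomTruth <- function(kind, params, seed, truth) {
  new("PhantomTruth", kind = kind, params = params,
      seed = as.integer(seed), truth = truth)
}
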