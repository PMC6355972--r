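#' @name accessors
#' @title Accessors for cellvol3d classes
#'
#' @description Slot access for [ImageStack-class], [LabeledMask-class],
#' [TraceRecord-class] and [PhantomTruth-class] objects goes through
#' these generics; user code should never reach into slots directly.
#'
#' @param x an object of the relevant class.
#' @param name channel name (for `channelData`).
#' @return `stackData`: the full 4D array. `channelData`: one channel as
#'   a 3D `(y, x, z)` array. `spacingUm`: named voxel pitch in
#'   micrometres. `channelNames`: character. `maskLabels`: integer 3D
#'   array. `provenance`, `qcFlags`: segmentation audit trail.
#'   `truthValues`, `phantomParams`, `phantomKind`, `phantomSeed`:
#'   phantom ground truth. `traceData`: the trace as a data.frame.
NULL

#' @rdname accessors
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))
#' @rdname accessors
#' @export
setGeneric("spacingUm", function(x) standardGeneric("spacingUm"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("channelData", function(x, name) standardGeneric("channelData"))
#' @rdname accessors
#' @export
setGeneric("stackMeta", function(x) standardGeneric("stackMeta"))
#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setGeneric("truthValues", function(x) standardGeneric("truthValues"))
#' @rdname accessors
#' @export
setGeneric("phantomParams", function(x) standardGeneric("phantomParams"))
#' @rdname accessors
#' @export
setGeneric("phantomKind", function(x) standardGeneric("phantomKind"))
#' @rdname accessors
#' @export
setGeneric("phantomSeed", function(x) standardGeneric("phantomSeed"))
#' @rdname accessors
#' @export
setGeneric("traceData", function(x) standardGeneric("traceData"))

#' @rdname accessors
setMethod("stackData", "ImageStack", function(x) x@data)
#' @rdname accessors
setMethod("spacingUm", "ImageStack", function(x) x@spacing)
#' @rdname accessors
setMethod("spacingUm", "LabeledMask", function(x) x@spacing)
#' @rdname accessors
setMethod("channelNames", "ImageStack", function(x) x@channelNames)
#' @rdname accessors
setMethod("stackMeta", "ImageStack", function(x) x@meta)
#' @rdname accessors
setMethod("channelData", "ImageStack", function(x, name) {
  if (is.numeric(name)) {
    i <- as.integer(name)
  } else {
    i <- match(name, x@channelNames)
  }
  if (is.na(i) || i < 1L || i > dim(x@data)[4L])
    stop("unknown channel: ", name, " (have: ",
         paste(x@channelNames, collapse = ", "), ")")
  d <- dim(x@data)
  array(x@data[, , , i], dim = d[1:3])
})
#' @rdname accessors
setMethod("maskLabels", "LabeledMask", function(x) x@labels)
#' @rdname accessors
setMethod("provenance", "LabeledMask", function(x) x@provenance)
#' @rdname accessors
setMethod("qcFlags", "LabeledMask", function(x) x@qc)
#' @rdname accessors
setMethod("truthValues", "PhantomTruth", function(x) x@truth)
#' @rdname accessors
setMethod("phantomParams", "PhantomTruth", function(x) x@params)
#' @rdname accessors
setMethod("phantomKind", "PhantomTruth", function(x) x@kind)
#' @rdname accessors
setMethod("phantomSeed", "PhantomTruth", function(x) x@seed)
#' @rdname accessors
setMethod("traceData", "TraceRecord", function(x) {
  data.frame(time_s = x@time_s, stress_kPa = x@stress_kPa,
             strain = x@strain, phase = x@phase)
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d x %d x %d voxels, %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing (um): y=%.3g x=%.3g z=%.3g\n",
              object@spacing["y"], object@spacing["x"], object@spacing["z"]))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "LabeledMask", function(object) {
  n <- max(0L, max(object@labels))
  cat(sprintf("LabeledMask: %d label(s), dims %s\n", n,
              paste(dim(object@labels), collapse = " x ")))
  p <- object@provenance
  cat(sprintf("  threshold=%.4g method=%s connectivity=%d\n",
              p$threshold, p$method, p$connectivity))
  if (n > 0) {
    flagged <- sum(object@qc$touches_border | object@qc$touches_other_cell)
    cat(sprintf("  %d flagged by QC\n", flagged))
  }
})

setMethod("show", "TraceRecord", function(object) {
  cat(sprintf("TraceRecord: %d samples (%d ramp, %d hold), hold strain %.3g\n",
              length(object@time_s), sum(object@phase == "ramp"),
              sum(object@phase == "hold"), object@holdStrain))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth <%s> seed=%d\n", object@kind, object@seed))
  tv <- object@truth
  for (nm in names(tv)) {
    v <- tv[[nm]]
    cat(sprintf("  %s = %s\n", nm,
                if (is.numeric(v)) format(v, digits = 6) else as.character(v)))
  }
})
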