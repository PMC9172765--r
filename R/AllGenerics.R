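#' @name accessors
#' @title Accessors for VideoStack and FlowSequence objects
#' @description Small accessor generics for the package's containers.
#' @param x a [VideoStack-class] or [FlowSequence-class] object.
#' @param t frame index (1-based).
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setGeneric("frameIntervalMs", function(x) standardGeneric("frameIntervalMs"))
#' @rdname accessors
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, t) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("flowFields", function(x) standardGeneric("flowFields"))
#' @rdname accessors
#' @export
setGeneric("referenceIndex", function(x) standardGeneric("referenceIndex"))
#' @rdname accessors
#' @export
setGeneric("getField", function(x, t) standardGeneric("getField"))

#' @rdname accessors
setMethod("frames", "VideoStack", function(x) x@frames)
#' @rdname accessors
setMethod("bitDepth", "VideoStack", function(x) x@bitDepth)
#' @rdname accessors
setMethod("frameIntervalMs", "VideoStack", function(x) x@frameIntervalMs)
#' @rdname accessors
setMethod("tissueMask", "VideoStack", function(x) x@mask)
#' @rdname accessors
setMethod("nFrames", "VideoStack", function(x) dim(x@frames)[3])
#' @rdname accessors
setMethod("frameDim", "VideoStack", function(x) dim(x@frames)[1:2])
#' @rdname accessors
setMethod("getFrame", "VideoStack", function(x, t) x@frames[, , t])

#' @rdname accessors
setMethod("flowFields", "FlowSequence", function(x) x@fields)
#' @rdname accessors
setMethod("referenceIndex", "FlowSequence", function(x) x@referenceIndex)
#' @rdname accessors
setMethod("nFrames", "FlowSequence", function(x) dim(x@fields)[4])
#' @rdname accessors
setMethod("frameDim", "FlowSequence", function(x) dim(x@fields)[1:2])
#' @rdname accessors
setMethod("getField", "FlowSequence", function(x, t) x@fields[, , , t])

setMethod("show", "VideoStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "VideoStack '%s': %d frames of %d x %d (H x W), %s-bit, %.3g ms/frame%s\n",
    object@name, d[3], d[1], d[2], object@bitDepth, object@frameIntervalMs,
    if (is.null(object@mask)) "" else ", with tissue mask"
  ))
  rng <- range(object@frames)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "FlowSequence", function(object) {
  d <- dim(object@fields)
  mg <- sqrt(object@fields[, , 1, ]^2 + object@fields[, , 2, ]^2)
  cat(sprintf(
    "FlowSequence: %d fields of %d x %d px, reference frame %d (%s)\n",
    d[4], d[1], d[2], object@referenceIndex, object@convention
  ))
  cat(sprintf("  max |u| = %.3g px, mean |u| = %.3g px\n", max(mg), mean(mg)))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI: %d x %d box at (x = %g, y = %g), %s aggregation\n",
              object@size, object@size, object@centerX, object@centerY,
              object@aggregation))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  cat(sprintf("  pre-smoothing (kx, ky, kt): %s\n",
              paste(object@preSmooth, collapse = ", ")))
  cat(sprintf("  contrast kernel: %d px\n", object@contrastKernel))
  cat(sprintf("  flow smoothing (kx, ky, kt): %s\n",
              paste(object@flowSmooth, collapse = ", ")))
  cat(sprintf("  backend: %s, reference frame: %d\n", object@backend,
              object@referenceIndex))
  cat(sprintf("  normalization window: %g ms\n", object@normWindowMs))
})
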