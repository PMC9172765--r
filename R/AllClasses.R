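#' @useDynLib moco, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' VideoStack: a time-ordered grayscale frame stack
#'
#' Container for optical mapping videos.  Frames are stored as an
#' `H x W x T` numeric array indexed `[y, x, t]` (row = y, column = x,
#' 1-based, origin top-left).  Integer stacks carry their camera bit depth
#' (8, 12, 14 or 16); stacks normalized to `[0, 1]` carry the pseudo-depth
#' `"unit"`.
#'
#' @slot frames numeric array, `H x W x T`.
#' @slot bitDepth character, one of `"8"`, `"12"`, `"14"`, `"16"`, `"unit"`.
#' @slot frameIntervalMs positive number, time between frames in ms.
#' @slot mask `H x W` logical matrix (`TRUE` = tissue) or `NULL`.
#' @slot name free-text identifier.
#'
#' @export
setClass("VideoStack",
  representation(
    frames = "array",
    bitDepth = "character",
    frameIntervalMs = "numeric",
    mask = "ANY",
    name = "character"
  )
)

setValidity("VideoStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-D array (H x W x T)")
  if (any(d < 1L)) return("frames must have H >= 1, W >= 1, T >= 1")
  if (!object@bitDepth %in% c("8", "12", "14", "16", "unit")) {
    return("bitDepth must be one of '8', '12', '14', '16', 'unit'")
  }
  if (length(object@frameIntervalMs) != 1L || !is.finite(object@frameIntervalMs) ||
      object@frameIntervalMs <= 0) {
    return("frameIntervalMs must be a positive number")
  }
  v <- object@frames
  if (object@bitDepth == "unit") {
    if (any(!is.finite(v))) return("unit stacks must contain finite values")
  } else {
    top <- 2^as.integer(object@bitDepth) - 1
    if (any(!is.finite(v)) || any(v < 0) || any(v > top) || any(v != round(v))) {
      return(sprintf("integer stacks must hold whole numbers in [0, %d]", top))
    }
  }
  if (!is.null(object@mask)) {
    if (!is.logical(object@mask) || !identical(dim(object@mask), d[1:2])) {
      return("mask must be a logical H x W matrix")
    }
  }
  TRUE
})

#' Construct a VideoStack
#'
#' @param frames `H x W x T` numeric array (`[y, x, t]`), or an `H x W`
#'   matrix for a single-frame stack.
#' @param bitDepth `8`, `12`, `14`, `16`, or `"unit"` for values in
#'   `[0, 1]`.
#' @param frameIntervalMs time between frames in milliseconds.
#' @param mask optional `H x W` logical tissue mask.
#' @param name free-text identifier.
#' @return A [VideoStack-class] object.
#' @examples
#' v <- videoStack(array(runif(4 * 4 * 3), c(4, 4, 3)))
#' nFrames(v)
#' @export
videoStack <- function(frames, bitDepth = "unit", frameIntervalMs = 2,
                       mask = NULL, name = "") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("VideoStack",
    frames = frames, bitDepth = as.character(bitDepth),
    frameIntervalMs = as.numeric(frameIntervalMs), mask = mask, name = name
  )
}

#' FlowSequence: per-frame dense displacement fields
#'
#' Displacement fields `u(x, y, t)` in pixel units, measured from a
#' declared reference frame: image content at reference position
#' `(x, y)` appears at `(x + u_x, y + u_y)` in frame `t`
#' ("ref-to-frame" convention).  Fields are stored as an `H x W x 2 x T`
#' array with component 1 = `u_x` (columns) and component 2 = `u_y`
#' (rows); the field at the reference frame is identically zero.
#'
#' @slot fields numeric array, `H x W x 2 x T`.
#' @slot referenceIndex 1-based index of the reference frame.
#' @slot convention fixed tag `"ref-to-frame"`.
#'
#' @export
setClass("FlowSequence",
  representation(
    fields = "array",
    referenceIndex = "integer",
    convention = "character"
  )
)

setValidity("FlowSequence", function(object) {
  d <- dim(object@fields)
  if (length(d) != 4L || d[3] != 2L) {
    return("fields must be an H x W x 2 x T array")
  }
  if (any(!is.finite(object@fields))) return("fields must be finite")
  ri <- object@referenceIndex
  if (length(ri) != 1L || ri < 1L || ri > d[4]) {
    return("referenceIndex out of range")
  }
  if (!identical(object@convention, "ref-to-frame")) {
    return("convention must be 'ref-to-frame'")
  }
  if (any(object@fields[, , , ri] != 0)) {
    return("field at the reference frame must be identically zero")
  }
  TRUE
})

#' Construct a FlowSequence
#'
#' @param fields `H x W x 2 x T` numeric array of displacements in pixels.
#' @param referenceIndex 1-based reference frame index.
#' @return A [FlowSequence-class] object.
#' @export
flowSequence <- function(fields, referenceIndex = 1L) {
  new("FlowSequence",
    fields = fields, referenceIndex = as.integer(referenceIndex),
    convention = "ref-to-frame"
  )
}

#' ROI: a square region of interest
#'
#' A `size x size` pixel box centred at (`centerX`, `centerY`) (1-based
#' pixel coordinates, x = column).  For even sizes the box extends one
#' pixel further towards larger coordinates.  Traces are the mean
#' intensity over the box clipped to the image bounds.
#'
#' @slot centerX,centerY numeric pixel coordinates.
#' @slot size side length in pixels (default 6).
#' @slot aggregation fixed tag `"mean"`.
#' @export
setClass("ROI",
  representation(centerX = "numeric", centerY = "numeric", size = "integer",
                 aggregation = "character")
)

setValidity("ROI", function(object) {
  if (object@size < 1L) return("size must be >= 1")
  if (!identical(object@aggregation, "mean")) return("aggregation must be 'mean'")
  TRUE
})

#' @rdname ROI-class
#' @param centerX,centerY centre of the box in pixel coordinates.
#' @param size side length in pixels.
#' @return An [ROI-class] object.
#' @export
roi <- function(centerX, centerY, size = 6L) {
  new("ROI", centerX = as.numeric(centerX), centerY = as.numeric(centerY),
      size = as.integer(size), aggregation = "mean")
}

#' PipelineConfig: parameters of the compensation pipeline
#'
#' Bundles the tunable parameters of the motion-compensation pipeline:
#' spatio-temporal pre-smoothing kernel diameters, contrast-enhancement
#' kernel diameter, flow-smoothing kernel diameters, backend name,
#' reference frame and the sliding-window length used for pixel-wise
#' normalization.
#'
#' @slot preSmooth integer triple `(k_x, k_y, k_t)`, odd diameters.
#' @slot contrastKernel odd integer disc diameter for contrast enhancement.
#' @slot flowSmooth integer triple `(k_x, k_y, k_t)`, odd diameters.
#' @slot backend flow backend name.
#' @slot referenceIndex 1-based reference frame index.
#' @slot normWindowMs sliding-window length in ms.
#' @slot epsilonFlat flat-region guard for normalizations.
#' @export
setClass("PipelineConfig",
  representation(
    preSmooth = "integer", contrastKernel = "integer", flowSmooth = "integer",
    backend = "character", referenceIndex = "integer",
    normWindowMs = "numeric", epsilonFlat = "numeric"
  )
)

setValidity("PipelineConfig", function(object) {
  kk <- c(object@preSmooth, object@contrastKernel, object@flowSmooth)
  if (length(object@preSmooth) != 3L || length(object@flowSmooth) != 3L) {
    return("preSmooth and flowSmooth must be integer triples")
  }
  if (any(kk < 1L) || any(kk %% 2L == 0L)) {
    return("all kernel diameters must be odd and >= 1")
  }
  if (object@normWindowMs <= 0) return("normWindowMs must be > 0")
  if (object@referenceIndex < 1L) return("referenceIndex must be >= 1")
  if (object@epsilonFlat <= 0) return("epsilonFlat must be > 0")
  TRUE
})

#' @rdname PipelineConfig-class
#' @param preSmooth,flowSmooth odd kernel diameters `(k_x, k_y, k_t)`.
#' @param contrastKernel odd disc diameter in pixels.
#' @param backend flow backend name (see [listFlowBackends()]).
#' @param referenceIndex 1-based reference frame index.
#' @param normWindowMs sliding-window length in ms.
#' @param epsilonFlat flat-region guard.
#' @return A [PipelineConfig-class] object.
#' @export
pipelineConfig <- function(preSmooth = c(3L, 3L, 3L), contrastKernel = 7L,
                           flowSmooth = c(3L, 3L, 3L), backend = "farneback",
                           referenceIndex = 1L, normWindowMs = 20,
                           epsilonFlat = 1e-6) {
  new("PipelineConfig",
    preSmooth = as.integer(preSmooth), contrastKernel = as.integer(contrastKernel),
    flowSmooth = as.integer(flowSmooth), backend = backend,
    referenceIndex = as.integer(referenceIndex),
    normWindowMs = as.numeric(normWindowMs), epsilonFlat = as.numeric(epsilonFlat)
  )
}
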