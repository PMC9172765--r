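#' Warp a frame by a displacement field
#'
#' Output-looks-up-source sampling: `out(x, y) = frame(x + u_x(x, y),
#' y + u_y(x, y))` with the chosen interpolation; sampling positions
#' outside the image clamp to the edge.  With a field estimated
#' ref-to-frame this pulls the deformed frame back into the reference
#' configuration, so estimation and warping form a closed loop with no
#' field inversion.  Bilinear interpolation is the default because even
#' sub-pixel resampling errors reintroduce motion artifacts.
#'
#' @param frame numeric matrix.
#' @param field `H x W x 2` displacement array (`[, , 1]` = `u_x`).
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return Float-valued matrix of the same shape.
#' @export
warpFrame <- function(frame, field, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!identical(dim(field), c(dim(frame), 2L))) {
    stop("field shape must be H x W x 2 matching the frame")
  }
  .warp_frame_cpp(frame, field[, , 1], field[, , 2],
                  interpolation == "bilinear")
}

#' Motion-compensate a video
#'
#' Warps every raw frame by its (smoothed) displacement field, producing
#' a stabilized video in the co-moving reference frame.  The reference
#' frame is returned unchanged.  Always warp the original raw frames --
#' never the contrast-enhanced frames used for estimation -- so the
#' measured fluorescence is preserved at full precision.
#'
#' @param stack a [VideoStack-class] (the raw video).
#' @param flow a [FlowSequence-class] with one field per frame.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return A float [VideoStack-class] with propagated metadata.
#' @export
compensateVideo <- function(stack, flow, interpolation = "bilinear") {
  stopifnot(is(stack, "VideoStack"), is(flow, "FlowSequence"))
  tt <- nFrames(stack)
  if (tt != nFrames(flow)) stop("video and flow frame counts differ")
  if (!identical(frameDim(stack), frameDim(flow))) stop("shape mismatch")
  out <- array(0, dim(stack@frames))
  ri <- flow@referenceIndex
  for (t in seq_len(tt)) {
    out[, , t] <- if (t == ri) {
      stack@frames[, , t]
    } else {
      warpFrame(stack@frames[, , t], flow@fields[, , , t], interpolation)
    }
  }
  videoStack(out, bitDepth = "unit", frameIntervalMs = stack@frameIntervalMs,
             mask = stack@mask, name = stack@name)
}

#' Run the full motion-compensation pipeline
#'
#' The standard processing order: the raw video is normalized to the unit
#' range, smoothed in space and time, locally contrast-enhanced, and the
#' flow backend estimates displacement fields of every frame against the
#' reference frame.  The fields are then spatio-temporally smoothed and
#' used to warp the *original raw* frames into the co-moving reference
#' frame.
#'
#' @param stack a [VideoStack-class] (raw video).
#' @param config a [PipelineConfig-class].
#' @param params named list overriding backend defaults.
#' @return List with elements `compensated` ([VideoStack-class]), `flow`
#'   (the smoothed [FlowSequence-class]) and `rawFlow` (unsmoothed fields,
#'   the ones accuracy metrics should be computed on).
#' @export
runCompensation <- function(stack, config = pipelineConfig(), params = list()) {
  stopifnot(is(stack, "VideoStack"), is(config, "PipelineConfig"))
  unit <- toUnitRange(stack, config@epsilonFlat)
  pre <- smoothSpatiotemporal(unit, config@preSmooth[1], config@preSmooth[2],
                              config@preSmooth[3])
  ce <- contrastEnhance(pre, config@contrastKernel, config@epsilonFlat)
  rawFlow <- estimateFlowVideo(ce, config@referenceIndex, config@backend,
                               params = params)
  flow <- smoothFlow(rawFlow, config@flowSmooth[1], config@flowSmooth[2],
                     config@flowSmooth[3])
  comp <- compensateVideo(unit, flow)
  list(compensated = comp, flow = flow, rawFlow = rawFlow)
}
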