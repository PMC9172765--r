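#' Pixel-wise sliding-window normalization
#'
#' Rescales each pixel's time trace by its minimum and maximum within a
#' sliding window of `windowMs` milliseconds
#' (`L = max(2, round(windowMs / frameIntervalMs))` frames), centred on
#' the current frame and truncated at the video ends.  Centred windows
#' avoid phase lag in upstroke timing.  Flat windows map to 0.  This
#' renders optical maps of propagating waves with uniform amplitude.
#'
#' @param stack a [VideoStack-class] with a known frame interval.
#' @param windowMs sliding-window length in ms (e.g. 20 ms = 10 frames at
#'   500 fps).
#' @param epsilonFlat flat-trace guard.
#' @return A `"unit"` [VideoStack-class] with values in `[0, 1]`.
#' @export
pixelwiseNormalize <- function(stack, windowMs = 20, epsilonFlat = 1e-6) {
  stopifnot(is(stack, "VideoStack"))
  if (windowMs <= 0) stop("windowMs must be > 0")
  L <- max(2L, as.integer(round(windowMs / stack@frameIntervalMs)))
  out <- .pixelwise_normalize_cpp(stack@frames, L, epsilonFlat)
  videoStack(out, bitDepth = "unit", frameIntervalMs = stack@frameIntervalMs,
             mask = stack@mask, name = stack@name)
}

#' Number of frames in a normalization window
#'
#' @param windowMs window length in ms.
#' @param frameIntervalMs frame interval in ms.
#' @return Integer window length in frames (at least 2).
#' @export
normWindowFrames <- function(windowMs, frameIntervalMs) {
  max(2L, as.integer(round(windowMs / frameIntervalMs)))
}

.roi_box <- function(roi, h, w) {
  half_lo <- floor((roi@size - 1) / 2)
  half_hi <- roi@size - 1 - half_lo
  ys <- (round(roi@centerY) - half_lo):(round(roi@centerY) + half_hi)
  xs <- (round(roi@centerX) - half_lo):(round(roi@centerX) + half_hi)
  list(ys = ys[ys >= 1 & ys <= h], xs = xs[xs >= 1 & xs <= w])
}

#' Extract an ROI trace
#'
#' Per-frame mean intensity over the ROI box clipped to the image bounds.
#'
#' @param stack a [VideoStack-class].
#' @param roi an [ROI-class].
#' @return Numeric vector of length `T`.
#' @export
extractTrace <- function(stack, roi) {
  stopifnot(is(stack, "VideoStack"), is(roi, "ROI"))
  d <- dim(stack@frames)
  box <- .roi_box(roi, d[1], d[2])
  if (length(box$ys) == 0L || length(box$xs) == 0L) {
    stop("ROI lies entirely outside the image")
  }
  apply(stack@frames[box$ys, box$xs, , drop = FALSE], 3, mean)
}

#' Average end-point error between two displacement fields
#'
#' The mean Euclidean distance between estimated and reference
#' displacement vectors, averaged over all pixel locations (or over an
#' optional tissue mask).  Accuracy benchmarks evaluate this on
#' *unsmoothed* fields.
#'
#' @param estimated,truth `H x W x 2` displacement arrays.
#' @param mask optional `H x W` logical inclusion mask.
#' @return Mean end-point error in pixels.
#' @export
computeEPE <- function(estimated, truth, mask = NULL) {
  if (!identical(dim(estimated), dim(truth))) stop("shape mismatch")
  err <- sqrt((estimated[, , 1] - truth[, , 1])^2 +
              (estimated[, , 2] - truth[, , 2])^2)
  if (is.null(mask)) mean(err) else mean(err[mask])
}
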