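#' Spatio-temporal box smoothing
#'
#' Smooths a video simultaneously in space and time: each output voxel is
#' the mean over the `kx x ky x kt` box centred on it, with replicate
#' padding at all borders.  The kernel is an unweighted box parameterized
#' by its diameters, applied separably.
#'
#' @param stack a [VideoStack-class] (any value domain; output is float).
#' @param kx,ky,kt odd kernel diameters in pixels / frames.
#' @return A smoothed [VideoStack-class] with the same shape and metadata.
#' @export
smoothSpatiotemporal <- function(stack, kx = 3L, ky = 3L, kt = 3L) {
  stopifnot(is(stack, "VideoStack"))
  .check_odd(c(kx, ky, kt))
  out <- .smooth_box3d_cpp(stack@frames, as.integer(kx), as.integer(ky),
                           as.integer(kt))
  videoStack(out, bitDepth = "unit", frameIntervalMs = stack@frameIntervalMs,
             mask = stack@mask, name = stack@name)
}

.check_odd <- function(k) {
  if (any(k < 1L) || any(k %% 2L == 0L)) {
    stop("kernel diameters must be odd and >= 1, got: ", paste(k, collapse = ", "))
  }
  invisible(TRUE)
}

#' Local contrast enhancement
#'
#' Renormalizes each pixel by the minimal and maximal intensities within a
#' small circular neighborhood:
#' `I_c = (I - min S) / (max S - min S)`, where `S` is the disc of pixels
#' within Euclidean distance `(k - 1) / 2` of the pixel (clipped at the
#' image borders).  Local grayvalue patterns are amplified to maximal
#' spatial contrast while spatially uniform temporal modulation -- such as
#' the fluorescence signal itself -- is suppressed, which protects the
#' brightness-constancy assumption of the flow backends.  Flat
#' neighborhoods (`max - min < epsilonFlat`) map to 0.
#'
#' The kernel diameter should match the image texture scale: around
#' 9-11 px for 320 x 440 videos, about 7 px at 256 x 256, and 3-5 px at
#' 128 x 128.  Too small a kernel amplifies noise; too large a kernel
#' flattens local contrast.
#'
#' @param stack a [VideoStack-class] or a single frame matrix.
#' @param k odd disc diameter in pixels (>= 3).
#' @param epsilonFlat flat-neighborhood guard.
#' @return A `"unit"` [VideoStack-class] (or matrix) with values in `[0, 1]`.
#' @export
contrastEnhance <- function(stack, k = 7L, epsilonFlat = 1e-6) {
  .check_odd(k)
  if (k < 3L) stop("contrast kernel must be >= 3")
  if (is.matrix(stack)) {
    return(.contrast_enhance_frame_cpp(stack, as.integer(k), epsilonFlat))
  }
  stopifnot(is(stack, "VideoStack"))
  v <- stack@frames
  out <- array(0, dim(v))
  for (t in seq_len(dim(v)[3])) {
    out[, , t] <- .contrast_enhance_frame_cpp(v[, , t], as.integer(k), epsilonFlat)
  }
  videoStack(out, bitDepth = "unit", frameIntervalMs = stack@frameIntervalMs,
             mask = stack@mask, name = stack@name)
}
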