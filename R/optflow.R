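.backend_registry <- new.env(parent = emptyenv())

#' Register a dense optical-flow backend
#'
#' Backends are registered by name and receive two same-shape unit-range
#' matrices (already quantized to the backend's input bit depth) plus a
#' parameter list; they must return `list(u = <H x W matrix>,
#' v = <H x W matrix>)` of displacements in pixels with the ref-to-frame
#' convention.  A backend may declare a minimum image size; smaller inputs
#' are bilinearly upscaled before estimation and the flow is downscaled
#' (and divided by the scale factors) afterwards.  Third-party backends
#' can be plugged in through this registry.
#'
#' @param name backend name.
#' @param fun estimation function `function(reference, frame, params)`.
#' @param inputBitDepth bit depth the backend expects (8 or 16).
#' @param minSize minimum image side length, or `NULL`.
#' @param defaults named list of default parameters.
#' @return Invisibly, `name`.
#' @export
registerFlowBackend <- function(name, fun, inputBitDepth = 8L, minSize = NULL,
                                defaults = list()) {
  assign(name, list(fun = fun, input_bit_depth = as.integer(inputBitDepth),
                    min_size = minSize, defaults = defaults),
         envir = .backend_registry)
  invisible(name)
}

#' List registered flow backends
#'
#' @return Character vector of backend names.
#' @export
listFlowBackends <- function() sort(ls(.backend_registry))

.get_backend <- function(name) {
  if (!exists(name, envir = .backend_registry, inherits = FALSE)) {
    stop("unknown backend: ", name, " (registered: ",
         paste(listFlowBackends(), collapse = ", "), ")")
  }
  get(name, envir = .backend_registry, inherits = FALSE)
}

.register_builtin_backends <- function() {
  lk <- function(reference, frame, params) {
    .flow_lk_cpp(reference, frame, params$levels, params$window,
                 params$iterations, params$eigThreshold)
  }
  lk_defaults <- list(levels = 4L, window = 15L, iterations = 3L,
                      eigThreshold = 1e-4)
  registerFlowBackend("lucas_kanade", lk, defaults = lk_defaults)
  registerFlowBackend("lucas_kanade_native", lk, defaults = lk_defaults)
  registerFlowBackend("farneback", function(reference, frame, params) {
    .flow_farneback_cpp(reference, frame, params$pyrScale, params$levels,
                        params$winsize, params$iterations, params$polyN,
                        params$polySigma)
  }, defaults = list(pyrScale = 0.5, levels = 5L, winsize = 13L,
                     iterations = 10L, polyN = 5L, polySigma = 1.1))
  registerFlowBackend("tvl1", function(reference, frame, params) {
    .flow_tvl1_cpp(reference, frame, params$tau, params$lambda, params$theta,
                   params$nscales, params$warps, params$epsilon,
                   params$maxIterations, params$useMedian)
  }, defaults = list(tau = 0.25, lambda = 0.15, theta = 0.3, nscales = 5L,
                     warps = 5L, epsilon = 0.01, maxIterations = 100L,
                     useMedian = TRUE))
  registerFlowBackend("brox", function(reference, frame, params) {
    .flow_brox_cpp(reference, frame, params$alpha, params$gamma,
                   params$scaleFactor, params$innerIterations,
                   params$outerIterations, params$solverIterations)
  }, inputBitDepth = 16L,
     defaults = list(alpha = 0.197, gamma = 10, scaleFactor = 0.75,
                     innerIterations = 5L, outerIterations = 10L,
                     solverIterations = 10L))
}

.merge_params <- function(defaults, params) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown backend parameter(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(params)] <- params
  defaults
}

.to_unit_pair <- function(reference, frame) {
  mx <- max(reference, frame)
  # values up to 2 are treated as unit-scale (unclipped noise may exceed 1
  # slightly; quantization clips later); larger values as camera integers
  if (mx <= 2) return(list(reference, frame))
  scale <- if (mx <= 255) 255 else if (mx <= 4095) 4095 else
           if (mx <= 16383) 16383 else 65535
  list(reference / scale, frame / scale)
}

#' Estimate dense optical flow between two frames
#'
#' Computes the displacement field between a reference frame and a second
#' frame with the named backend: image content at reference position
#' `(x, y)` appears at `(x + u_x, y + u_y)` in `frame`.  Inputs are
#' quantized to the backend's input bit depth before estimation (8-bit for
#' all builtin backends except `"brox"`, which receives 16-bit), then
#' scaled back to `[0, 1]`.
#'
#' @param reference,frame same-shape numeric matrices (unit-range floats
#'   or non-negative integers).
#' @param backend backend name, see [listFlowBackends()].
#' @param params named list overriding backend defaults.
#' @param quantize set `FALSE` to skip the bit-depth quantization.
#' @return `H x W x 2` array: `[, , 1]` = `u_x`, `[, , 2]` = `u_y`, pixels.
#' @export
estimateFlowPair <- function(reference, frame, backend = "farneback",
                             params = list(), quantize = TRUE) {
  if (!identical(dim(reference), dim(frame))) {
    stop("reference and frame must have the same shape")
  }
  be <- .get_backend(backend)
  p <- .merge_params(be$defaults, params)
  pr <- .to_unit_pair(reference, frame)
  if (quantize) {
    pr <- lapply(pr, quantizeFrame, bits = be$input_bit_depth)
  }
  h <- nrow(reference)
  w <- ncol(reference)
  sy <- sx <- 1
  if (!is.null(be$min_size) && min(h, w) < be$min_size) {
    fac <- ceiling(be$min_size / min(h, w))
    nh <- h * fac
    nw <- w * fac
    pr <- lapply(pr, .resize_bilinear_cpp, nh = nh, nw = nw)
    sy <- nh / h
    sx <- nw / w
  }
  fl <- be$fun(pr[[1]], pr[[2]], p)
  u <- fl$u
  v <- fl$v
  if (sx != 1 || sy != 1) {
    u <- .resize_bilinear_cpp(u, h, w) / sx
    v <- .resize_bilinear_cpp(v, h, w) / sy
  }
  out <- array(0, c(h, w, 2L))
  out[, , 1] <- u
  out[, , 2] <- v
  out
}

#' Estimate flow for every frame of a video
#'
#' Computes displacement fields of every frame with respect to a fixed
#' reference frame (first frame or any arbitrary frame).  Frames are
#' processed independently, direct-to-reference (no temporal chaining);
#' the field at the reference frame is exactly zero.
#'
#' @param stack a [VideoStack-class].
#' @param referenceIndex 1-based reference frame index.
#' @param backend backend name.
#' @param params named list overriding backend defaults.
#' @return A [FlowSequence-class].
#' @export
estimateFlowVideo <- function(stack, referenceIndex = 1L, backend = "farneback",
                              params = list()) {
  stopifnot(is(stack, "VideoStack"))
  tt <- nFrames(stack)
  if (referenceIndex < 1L || referenceIndex > tt) {
    stop("referenceIndex out of range: ", referenceIndex)
  }
  d <- frameDim(stack)
  ref <- getFrame(stack, referenceIndex)
  fields <- array(0, c(d[1], d[2], 2L, tt))
  for (t in seq_len(tt)) {
    if (t == referenceIndex) next
    fields[, , , t] <- estimateFlowPair(ref, getFrame(stack, t),
                                        backend = backend, params = params)
  }
  flowSequence(fields, referenceIndex)
}

#' Native coarse-to-fine dense Lucas-Kanade tracker
#'
#' Builds factor-2 image pyramids (the level count is capped at
#' `floor(log2(min(H, W) / 32)) + 1`), starts from zero flow at the
#' coarsest level, and at each level iteratively warps `frame` by the
#' current flow and solves the per-pixel 2x2 Lucas-Kanade normal
#' equations over an unweighted square window.  Pixels whose structure
#' tensor is nearly singular (smaller eigenvalue of the window-averaged
#' tensor below `eigThreshold`) keep the incoming upsampled flow; between
#' levels the flow is bilinearly upsampled and doubled.
#'
#' @param reference,frame same-shape matrices in `[0, 1]`.
#' @param levels requested pyramid levels (>= 1).
#' @param window odd window diameter (>= 5).
#' @param iterations warp/solve passes per level.
#' @param eigThreshold structure-tensor eigenvalue fallback threshold.
#' @return `H x W x 2` displacement array in pixels.
#' @export
densePyramidalLK <- function(reference, frame, levels = 4L, window = 15L,
                             iterations = 3L, eigThreshold = 1e-4) {
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 5L) stop("window must be >= 5")
  if (levels < 1L) stop("levels must be >= 1")
  if (!identical(dim(reference), dim(frame))) stop("shape mismatch")
  fl <- .flow_lk_cpp(reference, frame, as.integer(levels), as.integer(window),
                     as.integer(iterations), eigThreshold)
  out <- array(0, c(dim(reference), 2L))
  out[, , 1] <- fl$u
  out[, , 2] <- fl$v
  out
}

#' Spatio-temporally smooth a flow sequence
#'
#' Applies [smoothSpatiotemporal()] box smoothing to each displacement
#' component independently and re-zeroes the reference-frame field
#' afterwards.
#'
#' @param flow a [FlowSequence-class].
#' @param kx,ky,kt odd kernel diameters.
#' @return A smoothed [FlowSequence-class].
#' @export
smoothFlow <- function(flow, kx = 3L, ky = 3L, kt = 3L) {
  stopifnot(is(flow, "FlowSequence"))
  .check_odd(c(kx, ky, kt))
  f <- flow@fields
  out <- array(0, dim(f))
  for (comp in 1:2) {
    out[, , comp, ] <- .smooth_box3d_cpp(
      array(f[, , comp, ], dim(f)[c(1, 2, 4)]),
      as.integer(kx), as.integer(ky), as.integer(kt)
    )
  }
  out[, , , flow@referenceIndex] <- 0
  flowSequence(out, flow@referenceIndex)
}
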