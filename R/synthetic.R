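#' @title Synthetic optical-mapping scenes with exact ground truth
#'
#' @description
#' The synthetic module renders evaluation data for which the true
#' displacements are known analytically: a static tissue texture
#' `I_texture(x, y)` is modulated by a propagating excitation wave
#' `v(x, y, t)` in `[0, 1]` as
#' `I~(x, y, t) = (1 + f * v(x, y, t)) * I_texture(x, y)`
#' (fluorescence strength `f` = fractional change in fluorescence dF/F,
#' negative for a dye darkening on depolarization), deformed by a smooth
#' displacement field `d(x, y, t)`, and optionally degraded by additive
#' Gaussian noise.  It is a parametric stand-in for an electromechanical
#' tissue simulation: amplitudes and smoothness are bounded so the field
#' inversion converges and flow backends operate in their valid regime.
#'
#' @name synthetic
NULL

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' WaveModel: parametric excitation wave
#'
#' Action-potential-like pulse `A(s) = N (1 - exp(-s / tauR)) exp(-s / tauD)`
#' (normalized to peak 1) evaluated at the time since arrival
#' `s = t - arrival(x, y)`, repeating with period `period`.  Planar waves
#' arrive at `(x cos(theta) + y sin(theta)) / speed`; spiral waves derive
#' the arrival from the spiral phase
#' `chi = atan2(y - cy, x - cx) - r / pitch`, `s = t - chi / omega`.
#'
#' @slot kind `"planar"` or `"spiral"`.
#' @slot speed planar conduction speed, px/frame.
#' @slot direction planar propagation direction, radians.
#' @slot omega spiral angular frequency, rad/frame.
#' @slot pitch spiral pitch, px/rad.
#' @slot period repetition period, frames.
#' @slot upstroke rise time constant `tauR`, frames.
#' @slot decay decay time constant `tauD`, frames.
#' @slot origin `(cx, cy)` wave origin in pixels.
#' @export
setClass("WaveModel",
  representation(kind = "character", speed = "numeric", direction = "numeric",
                 omega = "numeric", pitch = "numeric", period = "numeric",
                 upstroke = "numeric", decay = "numeric", origin = "numeric")
)

setValidity("WaveModel", function(object) {
  if (!object@kind %in% c("planar", "spiral")) return("kind must be planar or spiral")
  if (object@period <= 0 || object@upstroke <= 0 || object@decay <= 0) {
    return("all time constants must be > 0")
  }
  TRUE
})

#' @rdname WaveModel-class
#' @param kind,speed,direction,omega,pitch,period,upstroke,decay,origin see slots.
#' @return A `WaveModel`.
#' @export
waveModel <- function(kind = "planar", speed = 0.5, direction = 0,
                      omega = 2 * pi / 150, pitch = 8, period = 150,
                      upstroke = 3, decay = 25, origin = c(64, 64)) {
  new("WaveModel", kind = kind, speed = speed, direction = direction,
      omega = omega, pitch = pitch, period = period, upstroke = upstroke,
      decay = decay, origin = as.numeric(origin))
}

.ap_pulse <- function(s, tauR, tauD) {
  speak <- tauR * log(1 + tauD / tauR)
  n <- 1 / ((1 - exp(-speak / tauR)) * exp(-speak / tauD))
  n * (1 - exp(-s / tauR)) * exp(-s / tauD)
}

#' Evaluate the excitation wave at one time point
#'
#' @param model a [WaveModel-class].
#' @param t time in frames (first frame is `t = 0`).
#' @param dim image dimensions `c(H, W)`.
#' @return `H x W` matrix with values in `[0, 1]` (0 before first arrival).
#' @export
waveField <- function(model, t, dim) {
  h <- dim[1]
  w <- dim[2]
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  arrival <- if (model@kind == "planar") {
    (x * cos(model@direction) + y * sin(model@direction)) / model@speed
  } else {
    r <- sqrt((x - model@origin[1])^2 + (y - model@origin[2])^2)
    chi <- atan2(y - model@origin[2], x - model@origin[1]) - r / model@pitch
    chi / model@omega
  }
  s <- t - arrival
  v <- matrix(0, h, w)
  pos <- s >= 0
  v[pos] <- .ap_pulse(s[pos] %% model@period, model@upstroke, model@decay)
  pmin(pmax(v, 0), 1)
}

#' DeformationModel: parametric tissue deformation
#'
#' `"bulk"`: a seeded smooth random vector field `g(x, y)` (unit-normalized
#' maximum magnitude) scaled by `sin(2 pi t / period)`, emulating global
#' tissue motion.  `"contractile"`: the excitation is low-pass filtered in
#' time (first-order, time constant `tauEm` frames, emulating
#' excitation-contraction coupling delay) into an activation field
#' `s(x, y, t)`, and the displacement is the negative gradient of its
#' Gaussian-smoothed version, `d = -A * grad(G_sigmaD * s)`, normalized so
#' `max |d| = A` at its peak.  Both constructions are spatially smooth by
#' design so the forward-field inversion converges.
#'
#' @slot kind `"bulk"` or `"contractile"`.
#' @slot amplitude peak displacement `A`, px.
#' @slot tauEm excitation-contraction delay, frames (contractile).
#' @slot sigmaD Gaussian width of the activation smoothing, px (contractile).
#' @slot profileSigma correlation scale of the bulk random field, px.
#' @slot seed RNG seed for the bulk profile.
#' @export
setClass("DeformationModel",
  representation(kind = "character", amplitude = "numeric", tauEm = "numeric",
                 sigmaD = "numeric", profileSigma = "numeric", seed = "integer")
)

setValidity("DeformationModel", function(object) {
  if (!object@kind %in% c("bulk", "contractile")) {
    return("kind must be bulk or contractile")
  }
  if (object@amplitude < 0) return("amplitude must be >= 0")
  TRUE
})

#' @rdname DeformationModel-class
#' @param kind,amplitude,tauEm,sigmaD,profileSigma,seed see slots.
#' @return A `DeformationModel`.
#' @export
deformationModel <- function(kind = "contractile", amplitude = 5, tauEm = 10,
                             sigmaD = 12, profileSigma = 16, seed = 1L) {
  new("DeformationModel", kind = kind, amplitude = amplitude, tauEm = tauEm,
      sigmaD = sigmaD, profileSigma = profileSigma, seed = as.integer(seed))
}

.central_grad <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  gx <- (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
  gy <- (m[c(2:h, h), ] - m[c(1, 1:(h - 1)), ]) / 2
  # one-sided differences at the borders (full step, not half)
  gx[, 1] <- m[, 2] - m[, 1]
  gx[, w] <- m[, w] - m[, w - 1]
  gy[1, ] <- m[2, ] - m[1, ]
  gy[h, ] <- m[h, ] - m[h - 1, ]
  list(gx = gx, gy = gy)
}

.deform_cache <- new.env(parent = emptyenv())

# Full deformation time series d(x, y, t), t = 0 .. duration-1, as an
# H x W x 2 x duration array; memoized on the model/wave parameters.
.deformation_series <- function(model, wave, dim, duration, mask = NULL) {
  key <- paste(c(model@kind, model@amplitude, model@tauEm, model@sigmaD,
                 model@profileSigma, model@seed, wave@kind, wave@speed,
                 wave@direction, wave@omega, wave@pitch, wave@period,
                 wave@upstroke, wave@decay, wave@origin, dim, duration,
                 if (is.null(mask)) "nomask" else c(sum(mask), sum(which(mask)))),
               collapse = "|")
  if (!is.null(.deform_cache[[key]])) return(.deform_cache[[key]])
  h <- dim[1]
  w <- dim[2]
  d <- array(0, c(h, w, 2L, duration))
  # smooth support window: the background does not deform, so the field is
  # tapered by the Gaussian-blurred tissue mask (kept smooth so the
  # inversion stays contractive)
  win <- if (is.null(mask)) {
    matrix(1, h, w)
  } else {
    .gaussian_blur_cpp(matrix(as.numeric(mask), h, w), model@sigmaD / 2)
  }
  if (model@amplitude > 0) {
    if (model@kind == "bulk") {
      g <- .with_seed(model@seed, {
        gx <- .gaussian_blur_cpp(matrix(stats::rnorm(h * w), h, w),
                                 model@profileSigma)
        gy <- .gaussian_blur_cpp(matrix(stats::rnorm(h * w), h, w),
                                 model@profileSigma)
        gx <- gx * win
        gy <- gy * win
        mag <- max(sqrt(gx^2 + gy^2))
        list(gx = gx / mag, gy = gy / mag)
      })
      for (t in seq_len(duration) - 1L) {
        s <- sin(2 * pi * t / wave@period)
        d[, , 1, t + 1L] <- model@amplitude * g$gx * s
        d[, , 2, t + 1L] <- model@amplitude * g$gy * s
      }
    } else {
      act <- matrix(0, h, w)
      raw <- array(0, c(h, w, 2L, duration))
      for (t in seq_len(duration) - 1L) {
        v <- waveField(wave, t, dim)
        act <- act + (v - act) / model@tauEm
        gr <- .central_grad(.gaussian_blur_cpp(act, model@sigmaD))
        raw[, , 1, t + 1L] <- -gr$gx * win
        raw[, , 2, t + 1L] <- -gr$gy * win
      }
      mag <- max(sqrt(raw[, , 1, ]^2 + raw[, , 2, ]^2))
      if (mag > 0) d <- model@amplitude * raw / mag
    }
  }
  # keep the cache to a handful of scenes
  if (length(ls(.deform_cache)) > 4L) rm(list = ls(.deform_cache), envir = .deform_cache)
  .deform_cache[[key]] <- d
  d
}

#' Evaluate the deformation field at one time point
#'
#' @param model a [DeformationModel-class].
#' @param wave the [WaveModel-class] driving contraction.
#' @param t time in frames (0-based).
#' @param dim image dimensions `c(H, W)`.
#' @param duration scene duration in frames (the contractile activation
#'   is integrated, and the amplitude normalized, over this horizon).
#' @param mask optional logical tissue mask; the field is tapered to zero
#'   over the background by a Gaussian-smoothed copy of the mask.
#' @return `H x W x 2` displacement array, `max |d| <= amplitude`.
#' @export
deformationField <- function(model, wave, t, dim, duration = 250L,
                             mask = NULL) {
  ser <- .deformation_series(model, wave, dim, as.integer(duration), mask)
  ser[, , , t + 1L]
}

#' Elliptical tissue mask
#'
#' @param h,w image dimensions.
#' @param inset fractional margin between the ellipse and the image edge.
#' @return `H x W` logical matrix, `TRUE` = tissue.
#' @export
ellipseMask <- function(h, w, inset = 0.08) {
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  a <- (w / 2) * (1 - inset)
  b <- (h / 2) * (1 - inset)
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

#' Generate a synthetic tissue texture
#'
#' Seeded white noise convolved with a Gaussian sized so the empirical
#' autocorrelation half-width equals `correlationLength`, affinely
#' rescaled so tissue pixels span `[0.2, 1.0]`; background pixels
#' (outside the mask) are set to 0.05.
#'
#' @param h,w image dimensions.
#' @param correlationLength spatial correlation length in px.
#' @param seed RNG seed.
#' @param mask optional logical tissue mask (default: all tissue).
#' @return `H x W` unit-range matrix.
#' @export
makeTexture <- function(h, w, correlationLength = 3, seed = 42L, mask = NULL) {
  stopifnot(correlationLength >= 1)
  # Gaussian width chosen so the autocorrelation half-width (where the
  # normalized autocorrelation drops to 0.5) equals correlationLength:
  # blurred white noise has autocorrelation exp(-r^2 / (4 sigma^2))
  sigma <- correlationLength / (2 * sqrt(log(2)))
  tex <- .with_seed(seed, {
    .gaussian_blur_cpp(matrix(stats::rnorm(h * w), h, w), sigma)
  })
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  rng <- range(tex[mask])
  out <- matrix(0.05, h, w)
  out[mask] <- 0.2 + 0.8 * (tex[mask] - rng[1]) / (rng[2] - rng[1])
  pmin(pmax(out, 0), 1)  # guard float epsilon at the extremes
}

#' SyntheticScene: full generator configuration
#'
#' @slot width,height image dimensions in px.
#' @slot texture `H x W` unit texture image.
#' @slot mask `H x W` logical tissue mask.
#' @slot wave a [WaveModel-class].
#' @slot deformation a [DeformationModel-class].
#' @slot f signed fractional fluorescence change dF/F (e.g. -0.05 = 5%
#'   darkening at full excitation).
#' @slot sigma additive Gaussian noise standard deviation on unit
#'   intensities.
#' @slot duration scene duration in frames.
#' @slot seed master RNG seed.
#' @export
setClass("SyntheticScene",
  representation(width = "integer", height = "integer", texture = "matrix",
                 mask = "matrix", wave = "WaveModel",
                 deformation = "DeformationModel", f = "numeric",
                 sigma = "numeric", duration = "integer", seed = "integer")
)

setValidity("SyntheticScene", function(object) {
  if (abs(object@f) > 0.5) return("|f| must be <= 0.5")
  if (object@sigma < 0) return("sigma must be >= 0")
  if (any(object@texture < 0) || any(object@texture > 1)) {
    return("texture must be in [0, 1]")
  }
  if (object@duration < 2L) return("duration must be >= 2")
  TRUE
})

#' @rdname SyntheticScene-class
#'
#' @details The default scene is a 128 x 128 px field of view with a
#' planar wave (0.5 px/frame, period 150 frames, upstroke 3, decay 25),
#' contractile deformation of 5 px peak amplitude (coupling delay 10
#' frames, activation smoothing 12 px) and a texture correlation length
#' of 3 px -- the desk-scale analogue of a 128 x 128 optical mapping
#' recording.  The duration of 250 frames lets the planar wave traverse
#' the full field of view at the default speed.
#'
#' @param width,height,f,sigma,duration,seed see slots.
#' @param wave a [WaveModel-class].
#' @param deformation a [DeformationModel-class].
#' @param correlationLength texture correlation length, px.
#' @return A `SyntheticScene`.
#' @export
syntheticScene <- function(width = 128L, height = 128L, wave = waveModel(),
                           deformation = deformationModel(), f = -0.05,
                           sigma = 0, duration = 250L, seed = 42L,
                           correlationLength = 3) {
  mask <- ellipseMask(height, width)
  texture <- makeTexture(height, width, correlationLength, seed = seed,
                         mask = mask)
  new("SyntheticScene", width = as.integer(width), height = as.integer(height),
      texture = texture, mask = mask, wave = wave, deformation = deformation,
      f = f, sigma = sigma, duration = as.integer(duration),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d x %d px, %s wave, %s deformation (A = %g px)\n",
    object@width, object@height, object@wave@kind, object@deformation@kind,
    object@deformation@amplitude
  ))
  cat(sprintf("  f = %g (dF/F), sigma = %g, duration = %d frames, seed = %d\n",
              object@f, object@sigma, object@duration, object@seed))
})

#' Render one synthetic frame
#'
#' Applies the fluorescence modulation
#' `(1 + f * v) * texture` on mask pixels; the background is returned
#' unchanged.
#'
#' @param texture `H x W` unit texture.
#' @param vField `H x W` excitation field in `[0, 1]`.
#' @param f fractional fluorescence change.
#' @param mask logical tissue mask (default: all tissue).
#' @return `H x W` unit-range matrix.
#' @export
renderFrame <- function(texture, vField, f, mask = NULL) {
  stopifnot(all(abs(f * vField) < 1))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(texture), ncol(texture))
  out <- texture
  out[mask] <- (1 + f * vField[mask]) * texture[mask]
  out
}

#' Add Gaussian noise
#'
#' Independent zero-mean Gaussian draws per pixel (and frame) on the unit
#' intensity scale.  Values are deliberately not clipped; quantization
#' clamps later if an integer conversion is requested.
#'
#' @param x matrix, array or [VideoStack-class].
#' @param sigma noise standard deviation.
#' @param seed RNG seed.
#' @return Same shape as the input.
#' @export
addNoise <- function(x, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (is(x, "VideoStack")) {
    out <- x
    out@frames <- addNoise(x@frames, sigma, seed)
    return(out)
  }
  if (sigma == 0) return(x)
  .with_seed(seed, x + array(stats::rnorm(length(x), 0, sigma), dim(x)))
}

#' Generate one evaluation image pair with ground truth
#'
#' The first image is the rendered frame at `t1`; the second is the
#' rendered frame at `t2` deformed by the ground-truth displacements
#' `u(x, y) = d(x, y, t2) - d(x, y, t1)`, constructed so that content at
#' position `(x, y)` of image A appears at `(x + u_x, y + u_y)` in image
#' B.  The forward deformation is realized by sampling at the inverse
#' mapping, obtained by fixed-point iteration (warm-started, at most 60 iterations,
#' convergence 1e-3 px).  Noise of standard deviation `scene@sigma` is
#' then added independently to A and B; the returned truth `u` is
#' noise-free and exact.
#'
#' @param scene a [SyntheticScene-class].
#' @param t1,t2 distinct time points in `[0, duration)`.
#' @param noiseSeed RNG seed for the noise draws (default: scene seed).
#' @return List with matrices `A`, `B`, the `H x W x 2` truth field `u`,
#'   and `t1`, `t2`.
#' @export
makePair <- function(scene, t1, t2, noiseSeed = NULL) {
  stopifnot(is(scene, "SyntheticScene"))
  if (t1 == t2) stop("t1 and t2 must differ")
  if (max(t1, t2) >= scene@duration || min(t1, t2) < 0) {
    stop("time points must lie in [0, duration)")
  }
  dm <- c(scene@height, scene@width)
  v1 <- waveField(scene@wave, t1, dm)
  v2 <- waveField(scene@wave, t2, dm)
  i1 <- renderFrame(scene@texture, v1, scene@f, scene@mask)
  i2 <- renderFrame(scene@texture, v2, scene@f, scene@mask)
  d1 <- deformationField(scene@deformation, scene@wave, t1, dm,
                         scene@duration, scene@mask)
  d2 <- deformationField(scene@deformation, scene@wave, t2, dm,
                         scene@duration, scene@mask)
  u <- d2 - d1
  inv <- .invert_flow_cpp(u[, , 1], u[, , 2], 60L, 1e-3)
  if (!inv$converged) {
    stop("non-convergent field inversion; deformation amplitude/gradient out of bounds")
  }
  b <- .warp_frame_cpp(i2, inv$u, inv$v, TRUE)
  if (scene@sigma > 0) {
    if (is.null(noiseSeed)) noiseSeed <- scene@seed
    noise <- .with_seed(noiseSeed, {
      list(matrix(stats::rnorm(length(i1), 0, scene@sigma), nrow(i1)),
           matrix(stats::rnorm(length(b), 0, scene@sigma), nrow(b)))
    })
    i1 <- i1 + noise[[1]]
    b <- b + noise[[2]]
  }
  list(A = i1, B = b, u = u, t1 = t1, t2 = t2)
}

#' Generate a dataset of evaluation pairs
#'
#' Draws `nPairs` pairs of distinct time points uniformly at random from
#' the scene duration; per-pair noise seeds are derived as
#' `seed + index`.  The same master seed reproduces the dataset exactly.
#'
#' @param scene a [SyntheticScene-class].
#' @param nPairs number of pairs (>= 1).
#' @param seed master seed.
#' @return List of [makePair()] results, with the scene attached as
#'   attribute `"scene"`.
#' @export
makeDataset <- function(scene, nPairs, seed = 1L) {
  stopifnot(nPairs >= 1)
  times <- .with_seed(seed, {
    t(vapply(seq_len(nPairs), function(i) {
      sample.int(scene@duration, 2L, replace = FALSE) - 1L
    }, integer(2)))
  })
  out <- lapply(seq_len(nPairs), function(i) {
    makePair(scene, times[i, 1], times[i, 2], noiseSeed = seed + i)
  })
  attr(out, "scene") <- scene
  out
}

#' Render a full synthetic video with ground-truth flow
#'
#' Frame `t` is the rendered, deformed (relative to `t = 0`), noise-added
#' image; the ground-truth [FlowSequence-class] (ref-to-frame convention,
#' reference = first frame) derives from `d(., ., t) - d(., ., 0)` and is
#' exactly zero at the reference frame.
#'
#' @param scene a [SyntheticScene-class].
#' @param nframes number of frames (>= 2, at most the scene duration).
#' @return List with `video` (a unit [VideoStack-class]) and `flow` (the
#'   ground-truth [FlowSequence-class]).
#' @export
makeVideo <- function(scene, nframes) {
  stopifnot(is(scene, "SyntheticScene"), nframes >= 2,
            nframes <= scene@duration)
  dm <- c(scene@height, scene@width)
  frames <- array(0, c(dm, nframes))
  fields <- array(0, c(dm, 2L, nframes))
  d0 <- deformationField(scene@deformation, scene@wave, 0, dm,
                         scene@duration, scene@mask)
  for (t in seq_len(nframes) - 1L) {
    v <- waveField(scene@wave, t, dm)
    img <- renderFrame(scene@texture, v, scene@f, scene@mask)
    if (t > 0) {
      dt <- deformationField(scene@deformation, scene@wave, t, dm,
                             scene@duration, scene@mask)
      u <- dt - d0
      inv <- .invert_flow_cpp(u[, , 1], u[, , 2], 60L, 1e-3)
      if (!inv$converged) stop("non-convergent field inversion")
      img <- .warp_frame_cpp(img, inv$u, inv$v, TRUE)
      fields[, , , t + 1L] <- u
    }
    if (scene@sigma > 0) img <- addNoise(img, scene@sigma, scene@seed + t)
    frames[, , t + 1L] <- img
  }
  list(
    video = videoStack(frames, bitDepth = "unit", frameIntervalMs = 2,
                       mask = scene@mask, name = "synthetic"),
    flow = flowSequence(fields, 1L)
  )
}
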