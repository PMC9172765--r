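#' Evaluate one backend on a dataset of image pairs
#'
#' For each pair the images are optionally contrast-enhanced, quantized to
#' the backend's input bit depth, the flow is estimated, and the end-point
#' error against the exact ground truth is computed on the *unsmoothed*
#' field (flow smoothing is a post-processing step for stabilization, not
#' part of the accuracy metric).
#'
#' @param dataset output of [makeDataset()] (optionally with noise added).
#' @param backend backend name.
#' @param contrastEnhanced apply [contrastEnhance()] to both images first.
#' @param ceKernel contrast-enhancement kernel diameter.
#' @param params backend parameter overrides.
#' @param mask optional EPE inclusion mask.
#' @return Numeric vector of per-pair mean EPEs, with attribute
#'   `"seconds_per_pair"` (flow estimation only).
#' @export
benchmarkBackend <- function(dataset, backend, contrastEnhanced = FALSE,
                             ceKernel = 5L, params = list(), mask = NULL) {
  epes <- numeric(length(dataset))
  secs <- 0
  for (i in seq_along(dataset)) {
    p <- dataset[[i]]
    a <- p$A
    b <- p$B
    if (contrastEnhanced) {
      a <- contrastEnhance(a, ceKernel)
      b <- contrastEnhance(b, ceKernel)
    }
    t0 <- proc.time()[["elapsed"]]
    est <- estimateFlowPair(a, b, backend = backend, params = params)
    secs <- secs + (proc.time()[["elapsed"]] - t0)
    epes[i] <- computeEPE(est, p$u, mask)
  }
  attr(epes, "seconds_per_pair") <- secs / length(dataset)
  epes
}

.bench_record <- function(backend, f_percent, sigma, ce, epes) {
  data.frame(
    backend = backend, f_percent = f_percent, sigma = sigma,
    contrast_enhanced = ce, mean_epe_px = mean(epes),
    n_pairs = length(epes),
    seconds_per_pair = attr(epes, "seconds_per_pair"),
    epe_se_px = stats::sd(epes) / sqrt(length(epes)),
    stringsAsFactors = FALSE
  )
}

.scene_with <- function(template, f = NULL, sigma = NULL) {
  if (!is.null(f)) template@f <- f
  if (!is.null(sigma)) template@sigma <- sigma
  validObject(template)
  template
}

#' Sweep fluorescence signal strength
#'
#' Reproduces the fluorescence-sensitivity experiment: for each
#' `(backend, |dF/F|, contrast-enhancement)` cell, a dataset of noise-free
#' synthetic pairs is generated at the given fluorescence strength (stored
#' as a darkening, `f = -f_percent / 100`), the flow is estimated, and the
#' mean end-point error is recorded.  Datasets are shared across backends
#' within a cell and reproduce bit-identically under a fixed master seed.
#'
#' @param backends character vector of backend names.
#' @param fValues fluorescence strengths `|dF/F|` in percent (0 to 50).
#' @param ceModes subset of `c(FALSE, TRUE)`: contrast enhancement off/on.
#' @param scene template [SyntheticScene-class] (its `f`, `sigma` are
#'   overridden per cell).
#' @param nPairs pairs per cell.
#' @param seed master seed.
#' @param ceKernel contrast-enhancement kernel diameter (default 5, the
#'   recommended size for the 128 x 128 default scene).
#' @return A `data.frame` of benchmark records, one row per cell, with a
#'   Monte-Carlo standard-error column.
#' @export
sweepFluorescence <- function(backends, fValues, ceModes = c(FALSE, TRUE),
                              scene = syntheticScene(), nPairs = 200L,
                              seed = 1L, ceKernel = 5L) {
  stopifnot(all(fValues >= 0), all(fValues <= 50), nPairs >= 1)
  rows <- list()
  for (f in fValues) {
    sc <- .scene_with(scene, f = -f / 100, sigma = 0)
    ds <- makeDataset(sc, nPairs, seed)
    for (ce in ceModes) {
      for (be in backends) {
        epes <- benchmarkBackend(ds, be, contrastEnhanced = ce,
                                 ceKernel = ceKernel)
        rows[[length(rows) + 1L]] <- .bench_record(be, f, 0, ce, epes)
      }
    }
  }
  do.call(rbind, rows)
}

#' Sweep additive noise strength
#'
#' Analogous to [sweepFluorescence()], sweeping the Gaussian noise
#' standard deviation at a fixed fluorescence strength.  The noise-free
#' base dataset is generated once per sweep, so the `sigma = 0` row is
#' identical to the corresponding fluorescence-sweep cell under the same
#' seed; noise is then re-drawn per sigma with derived seeds.
#'
#' @param backends character vector of backend names.
#' @param sigmaValues noise standard deviations on unit intensities.
#' @param scene template [SyntheticScene-class].
#' @param f fluorescence strength `|dF/F|` in percent.
#' @param nPairs pairs per cell.
#' @param seed master seed.
#' @param contrastEnhanced apply contrast enhancement (default off).
#' @param ceKernel contrast-enhancement kernel diameter.
#' @return A `data.frame` of benchmark records.
#' @export
sweepNoise <- function(backends, sigmaValues, scene = syntheticScene(), f = 3,
                       nPairs = 200L, seed = 1L, contrastEnhanced = FALSE,
                       ceKernel = 5L) {
  stopifnot(all(sigmaValues >= 0), nPairs >= 1)
  sc <- .scene_with(scene, f = -f / 100, sigma = 0)
  base <- makeDataset(sc, nPairs, seed)
  rows <- list()
  for (j in seq_along(sigmaValues)) {
    sg <- sigmaValues[j]
    ds <- base
    if (sg > 0) {
      for (i in seq_along(ds)) {
        noise_seed <- seed + 100000L * j + i
        noise <- .with_seed(noise_seed, {
          list(matrix(stats::rnorm(length(ds[[i]]$A), 0, sg), nrow(ds[[i]]$A)),
               matrix(stats::rnorm(length(ds[[i]]$B), 0, sg), nrow(ds[[i]]$B)))
        })
        ds[[i]]$A <- ds[[i]]$A + noise[[1]]
        ds[[i]]$B <- ds[[i]]$B + noise[[2]]
      }
    }
    for (be in backends) {
      epes <- benchmarkBackend(ds, be, contrastEnhanced = contrastEnhanced,
                               ceKernel = ceKernel)
      rows[[length(rows) + 1L]] <- .bench_record(be, f, sg, contrastEnhanced,
                                                 epes)
    }
  }
  do.call(rbind, rows)
}

#' Measure backend throughput
#'
#' Wall-clock per-pair processing time on synthetic frames, averaged after
#' 5 warm-up pairs, with and (optionally) without pre-/post-processing
#' (smoothing, contrast enhancement, flow smoothing and warping).
#' Report-only: timings are hardware-dependent.
#'
#' @param backend backend name.
#' @param imageSize side length of the square test frames.
#' @param nFrames number of timed frame pairs (>= 10).
#' @param includePrepost include the pre-/post-processing stages.
#' @param seed scene seed.
#' @return List with `fps`, `ms_per_pair`, `ms_sd`, `n`, `backend`,
#'   `include_prepost`.
#' @export
measureSpeed <- function(backend, imageSize = 128L, nFrames = 20L,
                         includePrepost = FALSE, seed = 1L) {
  stopifnot(nFrames >= 10)
  sc <- syntheticScene(width = imageSize, height = imageSize, seed = seed)
  ds <- makeDataset(sc, nFrames + 5L, seed)
  times <- numeric(length(ds))
  for (i in seq_along(ds)) {
    a <- ds[[i]]$A
    b <- ds[[i]]$B
    t0 <- proc.time()[["elapsed"]]
    if (includePrepost) {
      st <- videoStack(array(c(a, b), c(dim(a), 2L)))
      st <- smoothSpatiotemporal(st, 3L, 3L, 3L)
      st <- contrastEnhance(st, 7L)
      a <- getFrame(st, 1L)
      b <- getFrame(st, 2L)
    }
    fl <- estimateFlowPair(a, b, backend = backend)
    if (includePrepost) {
      fl[, , 1] <- .gaussian_blur_cpp(fl[, , 1], 1)
      fl[, , 2] <- .gaussian_blur_cpp(fl[, , 2], 1)
      invisible(warpFrame(ds[[i]]$B, fl))
    }
    times[i] <- proc.time()[["elapsed"]] - t0
  }
  timed <- times[-(1:5)]
  list(fps = 1 / mean(timed), ms_per_pair = 1000 * mean(timed),
       ms_sd = 1000 * stats::sd(timed), n = length(timed), backend = backend,
       include_prepost = includePrepost)
}

#' Write benchmark records to CSV
#'
#' Stable column order:
#' `backend,f_percent,sigma,contrast_enhanced,mean_epe_px,n_pairs,seconds_per_pair,epe_se_px`.
#'
#' @param records data.frame of benchmark records (possibly empty).
#' @param path output CSV file.
#' @return Invisibly, `path`.
#' @export
writeReport <- function(records, path) {
  cols <- c("backend", "f_percent", "sigma", "contrast_enhanced",
            "mean_epe_px", "n_pairs", "seconds_per_pair", "epe_se_px")
  if (is.null(records) || nrow(records) == 0L) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
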