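#' Read a grayscale video stack
#'
#' Reads a multi-page TIFF (8/16-bit integer or 32-bit float pages) or a
#' raw binary stack with an INI-style sidecar into a [VideoStack-class].
#' Pixel values are returned untouched.
#'
#' The raw dialect is a headerless little-endian binary file (one or two
#' bytes per pixel depending on bit depth, frames in raster-scan order)
#' next to a text sidecar `<path>.ini` with keys `width`, `height`,
#' `frames`, `bit_depth` and `frame_interval_ms`.
#'
#' @param path file to read.
#' @param formatHint optional `"tiff"` or `"raw"`; inferred from the file
#'   extension when missing.
#' @param frameIntervalMs frame interval to attach when the container does
#'   not carry one (TIFF); ignored for raw stacks.
#' @return A [VideoStack-class].
#' @export
readVideo <- function(path, formatHint = NULL, frameIntervalMs = 1) {
  if (!file.exists(path)) stop("unreadable video: file not found: ", path)
  fmt <- formatHint
  if (is.null(fmt)) {
    fmt <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) "tiff" else "raw"
  }
  if (fmt == "tiff") {
    pages <- tryCatch(
      tiff::readTIFF(path, all = TRUE, info = TRUE),
      error = function(e) stop("unreadable video: ", conditionMessage(e))
    )
    if (length(pages) == 0L) stop("unreadable video: no pages in TIFF")
    dims <- lapply(pages, dim)
    if (length(unique(dims)) != 1L) stop("inconsistent frame shapes in TIFF")
    bps <- attr(pages[[1]], "bits.per.sample")
    if (is.null(bps)) bps <- 8L
    depth <- switch(as.character(bps),
      "8" = "8", "16" = "16", "32" = "unit",
      stop("unsupported bit depth: ", bps)
    )
    if (depth != "unit") {
      # integer pages: re-read unscaled for bit-exact values
      pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
    }
    h <- dims[[1]][1]
    w <- dims[[1]][2]
    arr <- array(0, c(h, w, length(pages)))
    for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
    videoStack(arr, bitDepth = depth, frameIntervalMs = frameIntervalMs,
               name = basename(path))
  } else {
    meta <- .read_sidecar(path)
    need <- c("width", "height", "frames", "bit_depth", "frame_interval_ms")
    if (!all(need %in% names(meta))) {
      stop("sidecar is missing keys: ", paste(setdiff(need, names(meta)), collapse = ", "))
    }
    w <- as.integer(meta[["width"]])
    h <- as.integer(meta[["height"]])
    tt <- as.integer(meta[["frames"]])
    depth <- as.character(meta[["bit_depth"]])
    if (!depth %in% c("8", "12", "14", "16")) {
      stop("unsupported bit depth: ", depth)
    }
    bytes <- if (depth == "8") 1L else 2L
    n <- as.numeric(w) * h * tt
    vals <- readBin(path, "integer", n = n, size = bytes, signed = FALSE,
                    endian = "little")
    if (length(vals) != n) stop("unreadable video: raw stack truncated")
    arr <- array(0, c(h, w, tt))
    for (t in seq_len(tt)) {
      block <- vals[((t - 1) * w * h + 1):(t * w * h)]
      arr[, , t] <- t(matrix(block, nrow = w, ncol = h))  # raster-scan order
    }
    videoStack(arr, bitDepth = depth,
               frameIntervalMs = as.numeric(meta[["frame_interval_ms"]]),
               name = basename(path))
  }
}

.read_sidecar <- function(path) {
  sidecar <- paste0(path, ".ini")
  if (!file.exists(sidecar)) {
    sidecar <- sub("\\.[A-Za-z0-9]+$", ".ini", path)
  }
  if (!file.exists(sidecar)) stop("unreadable video: sidecar .ini not found for ", path)
  lines <- readLines(sidecar, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "[")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1))
  as.list(vals)
}

#' Write a video stack to disk
#'
#' Writes a multi-page TIFF (one page per frame) preserving the original
#' bit depth: 8-bit stacks become 8-bit pages, 12/14/16-bit stacks become
#' 16-bit pages, `"unit"` stacks become 32-bit float pages.  Paths ending
#' in `.raw` or `.bin` are written as a raw binary stack plus INI sidecar
#' instead (integer depths only).
#'
#' @param stack a [VideoStack-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeVideo <- function(stack, path) {
  stopifnot(is(stack, "VideoStack"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    stop("unwritable path: ", path)
  }
  if (grepl("\\.(raw|bin)$", path, ignore.case = TRUE)) {
    if (stack@bitDepth == "unit") stop("raw stacks require an integer bit depth")
    bytes <- if (stack@bitDepth == "8") 1L else 2L
    d <- dim(stack@frames)
    con <- file(path, "wb")
    on.exit(close(con))
    for (t in seq_len(d[3])) {
      writeBin(as.integer(t(stack@frames[, , t])), con, size = bytes,
               endian = "little")
    }
    writeLines(c(
      sprintf("width = %d", d[2]), sprintf("height = %d", d[1]),
      sprintf("frames = %d", d[3]), sprintf("bit_depth = %s", stack@bitDepth),
      sprintf("frame_interval_ms = %.10g", stack@frameIntervalMs)
    ), paste0(path, ".ini"))
  } else {
    d <- dim(stack@frames)
    if (stack@bitDepth == "unit") {
      pages <- lapply(seq_len(d[3]), function(t) stack@frames[, , t])
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    } else {
      bps <- if (stack@bitDepth == "8") 8L else 16L
      top <- 2^bps - 1
      pages <- lapply(seq_len(d[3]), function(t) stack@frames[, , t] / top)
      tiff::writeTIFF(pages, path, bits.per.sample = bps)
    }
  }
  invisible(path)
}

#' Write / read a displacement-field archive
#'
#' A [FlowSequence-class] is stored losslessly (R serialization) together
#' with its reference index and convention tag; the round trip is
#' bit-exact.  [readFlow()] refuses archives whose convention tag is
#' missing or different.
#'
#' @param flow a [FlowSequence-class].
#' @param path archive file (conventionally `.flow.rds`).
#' @return [readFlow()] returns a [FlowSequence-class]; [writeFlow()]
#'   returns `path` invisibly.
#' @export
writeFlow <- function(flow, path) {
  stopifnot(is(flow, "FlowSequence"))
  saveRDS(list(
    fields = flow@fields, reference_index = flow@referenceIndex,
    convention = flow@convention
  ), path)
  invisible(path)
}

#' @rdname writeFlow
#' @export
readFlow <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt flow archive: ", conditionMessage(e))
  })
  if (!is.list(obj) || is.null(obj$convention)) {
    stop("flow archive is missing its convention tag")
  }
  if (!identical(obj$convention, "ref-to-frame")) {
    stop("flow archive convention mismatch: ", obj$convention)
  }
  flowSequence(obj$fields, obj$reference_index)
}

#' Write ROI traces as a CSV table
#'
#' First column is time in ms (`(t - 1) * frameIntervalMs`), then one
#' column per labelled trace.
#'
#' @param traces named list of equal-length numeric vectors.
#' @param frameIntervalMs frame interval in ms.
#' @param path output CSV file.
#' @return Invisibly, `path`.
#' @export
writeTraces <- function(traces, frameIntervalMs, path) {
  if (length(traces) == 0L) {
    writeLines("time_ms", path)
    return(invisible(path))
  }
  lens <- lengths(traces)
  if (length(unique(lens)) != 1L) stop("traces have unequal lengths")
  if (is.null(names(traces)) || any(!nzchar(names(traces)))) {
    names(traces) <- paste0("trace", seq_along(traces))
  }
  df <- data.frame(time_ms = (seq_len(lens[1]) - 1) * frameIntervalMs)
  for (nm in names(traces)) df[[nm]] <- traces[[nm]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a stack to the unit range
#'
#' Rescales by the global (whole-video) minimum and maximum:
#' `(I - min) / (max - min)`.  If the video is flat
#' (`max - min < epsilonFlat`) an all-zero stack is returned.  Global
#' rather than per-frame scaling preserves temporal signals.
#'
#' @param stack a [VideoStack-class].
#' @param epsilonFlat flat-video guard.
#' @return A `"unit"` [VideoStack-class] with values in `[0, 1]`.
#' @export
toUnitRange <- function(stack, epsilonFlat = 1e-6) {
  stopifnot(is(stack, "VideoStack"))
  v <- stack@frames
  rng <- range(v)
  out <- if (rng[2] - rng[1] < epsilonFlat) {
    array(0, dim(v))
  } else {
    (v - rng[1]) / (rng[2] - rng[1])
  }
  videoStack(out, bitDepth = "unit", frameIntervalMs = stack@frameIntervalMs,
             mask = stack@mask, name = stack@name)
}

#' Quantize a stack to an integer bit depth
#'
#' Unit-range values `m` map to `floor(m * (2^bits - 1) + 0.5)` (round
#' half up, reproducible across platforms), clipped to the valid range.
#' Integer stacks are first normalized with [toUnitRange()].  Values
#' outside `[0, 1]` (e.g. unclipped noise) are clamped by the clipping.
#'
#' @param stack a [VideoStack-class].
#' @param bits target bit depth, 8 or 16.
#' @return An integer [VideoStack-class] of the requested depth.
#' @export
quantizeStack <- function(stack, bits = 8L) {
  stopifnot(is(stack, "VideoStack"), bits %in% c(8L, 16L))
  if (stack@bitDepth != "unit") stack <- toUnitRange(stack)
  top <- 2^bits - 1
  q <- pmin(pmax(floor(stack@frames * top + 0.5), 0), top)
  videoStack(q, bitDepth = as.character(bits),
             frameIntervalMs = stack@frameIntervalMs, mask = stack@mask,
             name = stack@name)
}

#' @rdname quantizeStack
#' @export
quantize8Bit <- function(stack) quantizeStack(stack, 8L)

#' Quantize a plain frame matrix
#'
#' Internal-facing helper used on image pairs: round-half-up quantization
#' of a unit-range matrix to `bits`, returned rescaled to `[0, 1]`
#' (value / (2^bits - 1)) so flow backends always see unit-scale inputs
#' with the quantization granularity applied.
#'
#' @param frame numeric matrix, nominally in `[0, 1]`.
#' @param bits target bit depth.
#' @return A matrix in `[0, 1]` on a `2^bits - 1` step grid.
#' @export
quantizeFrame <- function(frame, bits = 8L) {
  top <- 2^bits - 1
  pmin(pmax(floor(frame * top + 0.5), 0), top) / top
}
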