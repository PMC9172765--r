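test_that("VideoStack validity enforces shape, range and mask", {
  v <- videoStack(array(runif(4 * 5 * 3), c(4, 5, 3)), frameIntervalMs = 2)
  expect_s4_class(v, "VideoStack")
  expect_equal(nFrames(v), 3)
  expect_equal(frameDim(v), c(4, 5))
  expect_error(videoStack(array(-1, c(2, 2, 1)), bitDepth = 8), "integer stacks")
  expect_error(videoStack(array(300, c(2, 2, 1)), bitDepth = 8), "integer stacks")
  expect_error(
    videoStack(array(0.5, c(2, 2, 1)), mask = matrix(TRUE, 3, 3)),
    "mask"
  )
  expect_error(videoStack(array(0.5, c(2, 2, 1)), frameIntervalMs = 0), "positive")
})

test_that("FlowSequence requires a zero field at the reference frame", {
  f <- array(0, c(3, 3, 2, 4))
  f[, , , 2] <- 1
  fs <- flowSequence(f, 1L)
  expect_equal(referenceIndex(fs), 1L)
  expect_error(flowSequence(f, 2L), "reference")
  expect_error(flowSequence(array(0, c(3, 3, 3, 4))), "H x W x 2 x T")
})

test_that("TIFF round trips preserve shape and values across bit depths", {
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(tmp))
  for (depth in c("8", "16")) {
    top <- 2^as.integer(depth) - 1
    arr <- array(sample(0:top, 4 * 6 * 3, replace = TRUE), c(4, 6, 3))
    v <- videoStack(arr, bitDepth = depth, frameIntervalMs = 2)
    writeVideo(v, tmp)
    r <- readVideo(tmp, frameIntervalMs = 2)
    expect_identical(dim(frames(r)), dim(arr))
    expect_equal(frames(r), arr)
    expect_equal(bitDepth(r), depth)
  }
  # unit stacks go through 32-bit float pages
  arr <- array(runif(4 * 6 * 2), c(4, 6, 2))
  v <- videoStack(arr)
  writeVideo(v, tmp)
  r <- readVideo(tmp)
  expect_equal(bitDepth(r), "unit")
  expect_equal(frames(r), arr, tolerance = 1e-6)
  expect_equal(max(frames(r)), max(arr), tolerance = 1e-6)
})

test_that("12-bit-range data survives a 16-bit TIFF container exactly", {
  arr <- array(sample(0:4095, 8 * 8 * 2, replace = TRUE), c(8, 8, 2))
  v <- videoStack(arr, bitDepth = "12", frameIntervalMs = 2)
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(tmp))
  writeVideo(v, tmp)
  expect_equal(frames(readVideo(tmp)), arr)
})

test_that("raw stack + INI sidecar round trips bit-exactly", {
  arr <- array(sample(0:4095, 5 * 7 * 3, replace = TRUE), c(5, 7, 3))
  v <- videoStack(arr, bitDepth = "12", frameIntervalMs = 2.5)
  tmp <- tempfile(fileext = ".raw")
  on.exit(unlink(c(tmp, paste0(tmp, ".ini"))))
  writeVideo(v, tmp)
  r <- readVideo(tmp)
  expect_equal(frames(r), arr)
  expect_equal(bitDepth(r), "12")
  expect_equal(frameIntervalMs(r), 2.5)
})

test_that("unreadable or malformed inputs raise errors", {
  expect_error(readVideo(tempfile()), "unreadable")
  empty <- tempfile(fileext = ".tif")
  file.create(empty)
  on.exit(unlink(empty))
  expect_error(readVideo(empty), "unreadable")
  raw_no_sidecar <- tempfile(fileext = ".raw")
  writeBin(as.integer(1:4), raw_no_sidecar, size = 2)
  on.exit(unlink(raw_no_sidecar), add = TRUE)
  expect_error(readVideo(raw_no_sidecar), "sidecar")
})

test_that("flow archives round trip and refuse bad convention tags", {
  f <- array(rnorm(3 * 4 * 2 * 5), c(3, 4, 2, 5))
  f[, , , 2] <- 0
  fs <- flowSequence(f, 2L)
  tmp <- tempfile(fileext = ".flow.rds")
  on.exit(unlink(tmp))
  writeFlow(fs, tmp)
  r <- readFlow(tmp)
  expect_identical(flowFields(r), flowFields(fs))
  expect_identical(referenceIndex(r), 2L)
  # zero flow stays zero
  z <- flowSequence(array(0, c(2, 2, 2, 2)), 1L)
  writeFlow(z, tmp)
  expect_true(all(flowFields(readFlow(tmp)) == 0))
  # missing / wrong convention tag
  saveRDS(list(fields = f, reference_index = 2L), tmp)
  expect_error(readFlow(tmp), "convention")
  saveRDS(list(fields = f, reference_index = 2L, convention = "frame-to-ref"), tmp)
  expect_error(readFlow(tmp), "mismatch")
})

test_that("trace CSV output has a time column and rejects ragged traces", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  writeTraces(list(a = c(1, 2, 3), b = c(4, 5, 6)), 2, tmp)
  df <- read.csv(tmp)
  expect_equal(nrow(df), 3)
  expect_equal(df$time_ms, c(0, 2, 4))
  expect_equal(df$b, c(4, 5, 6))
  writeTraces(list(), 2, tmp)
  expect_equal(readLines(tmp), "time_ms")
  expect_error(writeTraces(list(a = 1:3, b = 1:2), 2, tmp), "unequal")
})

test_that("toUnitRange scales by the global video extrema", {
  arr <- array(100, c(4, 4, 3))
  arr[1, 1, 2] <- 4095
  v <- videoStack(arr, bitDepth = "12", frameIntervalMs = 2)
  u <- toUnitRange(v)
  expect_equal(bitDepth(u), "unit")
  expect_equal(frames(u)[1, 1, 2], 1.0)
  expect_equal(min(frames(u)), 0)
  expect_equal(max(frames(u)), 1)
  # direct-scan check on arbitrary data
  arr2 <- array(rnorm(4 * 4 * 3, 50, 10), c(4, 4, 3))
  u2 <- frames(toUnitRange(videoStack(arr2)))
  expect_equal(u2, (arr2 - min(arr2)) / (max(arr2) - min(arr2)))
  # idempotence on stacks already spanning [0, 1]
  expect_equal(frames(toUnitRange(toUnitRange(v))), frames(toUnitRange(v)))
  # flat guard
  flat <- toUnitRange(videoStack(array(0.7, c(3, 3, 2))))
  expect_true(all(frames(flat) == 0))
})

test_that("quantization rounds half up and preserves ordering", {
  v <- videoStack(array(c(0, 0.5, 1, 0.25), c(2, 2, 1)))
  q <- quantize8Bit(v)
  expect_equal(bitDepth(q), "8")
  expect_equal(as.vector(frames(q))[1:3], c(0, 128, 255))
  # monotone (non-strict) over a dense grid
  g <- seq(0, 1, length.out = 1001)
  qg <- quantizeFrame(matrix(g, 1)) * 255
  expect_true(all(diff(as.vector(qg)) >= 0))
  expect_true(all(qg >= 0 & qg <= 255))
  # integer stacks pass through unit normalization first
  vi <- videoStack(array(c(0, 2047.5, 4095, 1000), c(2, 2, 1)) * 2 / 2,
                   bitDepth = "unit")
  expect_true(all(frames(quantizeStack(toUnitRange(vi), 8L)) <= 255))
})
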