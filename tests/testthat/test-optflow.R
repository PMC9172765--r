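test_that("all registered builtin backends are listed", {
  expect_true(all(c("lucas_kanade", "lucas_kanade_native", "farneback",
                    "tvl1", "brox") %in% listFlowBackends()))
  expect_error(estimateFlowPair(matrix(0, 4, 4), matrix(0, 4, 4), "nope"),
               "unknown backend")
  expect_error(estimateFlowPair(matrix(0, 4, 4), matrix(0, 4, 5)), "shape")
})

test_that("identity pairs give near-zero flow on every backend", {
  a <- sinusoid_frame(64, 64)
  for (be in c("lucas_kanade", "farneback", "tvl1", "brox")) {
    fl <- estimateFlowPair(a, a, backend = be)
    expect_lt(mean(sqrt(fl[, , 1]^2 + fl[, , 2]^2)), 0.05)
  }
})

test_that("integer translations are recovered to < 0.1 px interior error", {
  a <- sinusoid_frame(96, 96)
  b <- sinusoid_frame(96, 96, dx = 3)
  for (be in c("lucas_kanade", "farneback", "tvl1", "brox")) {
    fl <- estimateFlowPair(a, b, backend = be)
    err <- sqrt((interior(fl[, , 1]) - 3)^2 + interior(fl[, , 2])^2)
    expect_lt(mean(err), 0.1)
  }
})

test_that("the native LK tracker resolves sub-pixel shifts", {
  a <- sinusoid_frame(96, 96)
  b <- sinusoid_frame(96, 96, dx = 0.5)
  fl <- densePyramidalLK(a, b)
  err <- sqrt((interior(fl[, , 1]) - 0.5)^2 + interior(fl[, , 2])^2)
  expect_lt(mean(err), 0.15)
  expect_error(densePyramidalLK(a, b, window = 14), "odd")
  expect_error(densePyramidalLK(a, b, window = 3), ">= 5")
})

test_that("textureless frames fall back to zero flow", {
  a <- matrix(0.5, 48, 48)
  fl <- densePyramidalLK(a, a + 1e-9)
  expect_true(all(fl == 0))
})

test_that("native LK is equivariant under common integer translation", {
  base <- sinusoid_frame(110, 110)
  a1 <- base[1:90, 1:90]
  b1 <- sinusoid_frame(110, 110, dx = 2)[1:90, 1:90]
  a2 <- base[11:100, 11:100]   # both inputs shifted by (10, 10)
  b2 <- sinusoid_frame(110, 110, dx = 2)[11:100, 11:100]
  f1 <- densePyramidalLK(a1, b1)
  f2 <- densePyramidalLK(a2, b2)
  expect_lt(mean(abs(interior(f1[, , 1], 20) - interior(f2[, , 1], 20))), 0.02)
})

test_that("video flow is direct-to-reference with an exactly zero reference field", {
  a <- sinusoid_frame(64, 64)
  arr <- array(0, c(64, 64, 3))
  arr[, , 1] <- a
  arr[, , 2] <- a
  arr[, , 3] <- sinusoid_frame(64, 64, dx = 2)
  v <- videoStack(arr, frameIntervalMs = 2)
  fs <- estimateFlowVideo(v, 1L, "lucas_kanade")
  expect_true(all(getField(fs, 1) == 0))
  expect_lt(mean(abs(getField(fs, 2))), 0.05)
  expect_lt(mean(abs(interior(getField(fs, 3)[, , 1]) - 2)), 0.1)
  expect_error(estimateFlowVideo(v, 4L), "out of range")
  # permuting non-reference frames permutes outputs (no temporal chaining)
  v2 <- videoStack(arr[, , c(1, 3, 2)], frameIntervalMs = 2)
  fs2 <- estimateFlowVideo(v2, 1L, "lucas_kanade")
  expect_equal(getField(fs2, 2), getField(fs, 3))
  expect_equal(getField(fs2, 3), getField(fs, 2))
})

test_that("static videos yield near-zero fields everywhere", {
  a <- sinusoid_frame(48, 48)
  v <- videoStack(array(rep(a, 4), c(48, 48, 4)), frameIntervalMs = 2)
  fs <- estimateFlowVideo(v, 2L, "farneback")
  expect_lt(max(abs(flowFields(fs))), 0.05)
})

test_that("a backend-declared minimum size triggers upscale and flow rescale", {
  # plug-in backend that reports a constant (1, 0) px displacement and
  # records the size it saw
  seen <- new.env()
  registerFlowBackend("const_probe", function(reference, frame, params) {
    seen$dim <- dim(reference)
    list(u = matrix(1, nrow(reference), ncol(reference)),
         v = matrix(0, nrow(reference), ncol(reference)))
  }, minSize = 160L)
  a <- sinusoid_frame(96, 96)
  fl <- estimateFlowPair(a, a, backend = "const_probe")
  expect_equal(seen$dim, c(192, 192))        # upscaled to >= 160
  expect_equal(dim(fl)[1:2], c(96, 96))      # flow back at native size
  expect_equal(mean(fl[, , 1]), 0.5, tolerance = 1e-6)  # divided by scale 2
})

test_that("unknown backend parameters are rejected", {
  a <- sinusoid_frame(48, 48)
  expect_error(estimateFlowPair(a, a, "farneback", params = list(bogus = 1)),
               "unknown backend parameter")
})

test_that("flow smoothing equals componentwise box smoothing and re-zeroes the reference", {
  set.seed(11)
  f <- array(rnorm(6 * 6 * 2 * 5), c(6, 6, 2, 5))
  f[, , , 3] <- 0
  fs <- flowSequence(f, 3L)
  sm <- smoothFlow(fs, 3, 3, 3)
  for (comp in 1:2) {
    expect_equal(flowFields(sm)[, , comp, c(1, 2, 4, 5)],
                 oracle_box3d(array(f[, , comp, ], c(6, 6, 5)), 3, 3, 3)[, , c(1, 2, 4, 5)],
                 tolerance = 1e-12)
  }
  expect_true(all(getField(sm, 3) == 0))
  # constant field is unchanged
  cf <- array(2, c(4, 4, 2, 3))
  cf[, , , 1] <- 0
  sm2 <- smoothFlow(flowSequence(cf, 1L), 3, 3, 1)
  expect_equal(getField(sm2, 2), cf[, , , 2])
})

test_that("8-bit quantization is applied before estimation", {
  # a sub-quantization-step contrast difference must be invisible
  a <- matrix(0.5, 48, 48)
  b <- a + 1e-4
  fl <- estimateFlowPair(a, b, backend = "lucas_kanade")
  expect_true(all(fl == 0))
})
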