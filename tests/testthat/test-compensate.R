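test_that("warping with a zero field is the identity to machine precision", {
  fr <- sinusoid_frame(32, 32)
  z <- array(0, c(32, 32, 2))
  expect_equal(warpFrame(fr, z), fr, tolerance = 1e-15)
  expect_equal(warpFrame(fr, z, "nearest"), fr, tolerance = 1e-15)
  expect_error(warpFrame(fr, array(0, c(16, 16, 2))), "shape")
})

test_that("an integer-shift field exactly cancels an integer translation", {
  a <- sinusoid_frame(48, 48)
  b <- sinusoid_frame(48, 48, dx = 3)   # content of a moved +3 in x
  fld <- array(0, c(48, 48, 2))
  fld[, , 1] <- 3
  rec <- warpFrame(b, fld)
  expect_equal(interior(rec, 4), interior(a, 4), tolerance = 1e-12)
})

test_that("bilinear sampling matches the closed form on a linear ramp", {
  ramp <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16, 16)
  fld <- array(0, c(16, 16, 2))
  fld[, , 1] <- 0.5
  out <- warpFrame(ramp, fld)
  # linear ramp: bilinear sample at x + 0.5 is the midpoint of neighbours
  expected <- (ramp + cbind(ramp[, -1], ramp[, 16])) / 2
  expect_equal(out[, 1:15], expected[, 1:15], tolerance = 1e-12)
  # nearest-neighbour rounds instead
  outn <- warpFrame(ramp, fld, "nearest")
  expect_equal(outn[, 1:14], ramp[, 2:15], tolerance = 1e-12)
})

test_that("compensating a static video with zero flow returns the input", {
  arr <- array(rep(sinusoid_frame(24, 24), 3), c(24, 24, 3))
  v <- videoStack(arr, frameIntervalMs = 2)
  z <- flowSequence(array(0, c(24, 24, 2, 3)), 1L)
  expect_equal(frames(compensateVideo(v, z)), arr)
  expect_error(compensateVideo(v, flowSequence(array(0, c(24, 24, 2, 2)), 1L)),
               "frame counts")
})

test_that("per-frame translations with matching fields recover the reference", {
  tt <- 4
  arr <- array(0, c(48, 48, tt))
  fields <- array(0, c(48, 48, 2, tt))
  for (t in seq_len(tt)) {
    arr[, , t] <- sinusoid_frame(48, 48, dx = t - 1)
    fields[, , 1, t] <- t - 1
  }
  v <- videoStack(arr, frameIntervalMs = 2)
  comp <- compensateVideo(v, flowSequence(fields, 1L))
  for (t in 2:tt) {
    expect_equal(interior(getFrame(comp, t), 6), interior(arr[, , 1], 6),
                 tolerance = 1e-10)
  }
})

test_that("ground-truth compensation recovers the undeformed rendering", {
  sc <- small_scene(f = -0.05)
  mv <- makeVideo(sc, 20)
  comp <- compensateVideo(mv$video, mv$flow)
  mae <- 0
  for (t in seq_len(20)) {
    img <- renderFrame(sc@texture, waveField(sc@wave, t - 1, c(48L, 48L)),
                       sc@f, sc@mask)
    mae <- mae + mean(abs(getFrame(comp, t) - img))
  }
  expect_lt(mae / 20, 0.02)
})

test_that("the pipeline estimates on contrast-enhanced frames but warps raw frames", {
  sc <- small_scene(f = -0.05)
  mv <- makeVideo(sc, 6)
  cfg <- pipelineConfig(backend = "lucas_kanade", contrastKernel = 5L)
  res <- runCompensation(mv$video, cfg)
  expect_s4_class(res$compensated, "VideoStack")
  expect_s4_class(res$flow, "FlowSequence")
  # warping the unit-range raw video with the smoothed flow must reproduce
  # the returned compensated stack exactly (raw frames, not CE frames)
  unit <- toUnitRange(mv$video)
  manual <- compensateVideo(unit, res$flow)
  expect_equal(frames(res$compensated), frames(manual), tolerance = 1e-12)
  # compensated frames stay on the raw intensity scale, CE frames do not
  expect_gt(min(getFrame(res$compensated, 2)[sc@mask]), 0.05)
  # rawFlow differs from the smoothed flow (smoothing really ran)
  expect_false(identical(flowFields(res$rawFlow), flowFields(res$flow)))
})
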