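test_that("textures are reproducible, bounded and correlated at the set scale", {
  m <- ellipseMask(64, 64)
  t1 <- makeTexture(64, 64, 3, seed = 7, mask = m)
  t2 <- makeTexture(64, 64, 3, seed = 7, mask = m)
  expect_identical(t1, t2)
  expect_true(all(t1 >= 0.05 & t1 <= 1))
  expect_equal(range(t1[m]), c(0.2, 1.0))
  expect_true(all(t1[!m] == 0.05))
  # autocorrelation half-width of the tissue fluctuation ~ correlation length
  for (cl in c(2, 4)) {
    tx <- makeTexture(96, 96, cl, seed = 8)
    center <- tx - mean(tx)
    ac <- sapply(0:8, function(lag) {
      a <- center[, 1:(96 - lag)]
      b <- center[, (1 + lag):96]
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    })
    half <- which(ac < 0.5)[1] - 1
    expect_lt(abs(half - cl), 0.3 * cl + 1)
  }
})

test_that("the excitation wave arrives, peaks at 1 and travels at the set speed", {
  wm <- waveModel(speed = 0.5, period = 100, upstroke = 3, decay = 12)
  dm <- c(32L, 64L)
  expect_true(all(waveField(wm, 0, dm)[, 2:64] == 0))   # before arrival
  v <- waveField(wm, 40, dm)
  expect_true(all(v >= 0 & v <= 1))
  expect_gt(max(v), 0.97)   # peak locus present (pixel-grid discretization)
  # the v = 0.5 upstroke crossing advances by c px/frame
  front <- function(t) {
    prof <- waveField(wm, t, dm)[16, ]
    max(which(prof > 0.5))
  }
  expect_equal(front(60) - front(40), 0.5 * 20, tolerance = 2)
  # spiral variant stays in range
  ws <- waveModel("spiral", omega = 2 * pi / 80, pitch = 6, period = 80,
                  upstroke = 3, decay = 12, origin = c(16, 16))
  vs <- waveField(ws, 30, c(32L, 32L))
  expect_true(all(vs >= 0 & vs <= 1))
})

test_that("deformation respects its amplitude bound and contracts after the wave", {
  sc <- small_scene()
  dm <- c(48L, 48L)
  zero <- deformationField(deformationModel(amplitude = 0), sc@wave, 10, dm,
                           90, sc@mask)
  expect_true(all(zero == 0))
  mx <- 0
  for (t in seq(0, 89, by = 5)) {
    d <- deformationField(sc@deformation, sc@wave, t, dm, 90, sc@mask)
    mx <- max(mx, max(sqrt(d[, , 1]^2 + d[, , 2]^2)))
  }
  expect_lte(mx, sc@deformation@amplitude + 1e-9)
  expect_gt(mx, 0.5 * sc@deformation@amplitude)  # normalization reaches A
  # the contractile activation (first-order low-pass of v, the drive of d)
  # lags the excitation by roughly tauEm at a fixed pixel
  vtrace <- sapply(0:89, function(t) waveField(sc@wave, t, dm)[24, 20])
  act <- numeric(90)
  acc <- 0
  for (t in seq_len(90)) {
    acc <- acc + (vtrace[t] - acc) / sc@deformation@tauEm
    act[t] <- acc
  }
  lag <- which.max(act) - which.max(vtrace)
  expect_gte(lag, sc@deformation@tauEm / 2)
  expect_lte(lag, 2 * sc@deformation@tauEm)
  # bulk deformation is zero at t = 0 (sin 0)
  bulk <- deformationModel("bulk", amplitude = 2)
  expect_true(all(deformationField(bulk, sc@wave, 0, dm, 90) == 0))
  b10 <- deformationField(bulk, sc@wave, 10, dm, 90)
  expect_gt(max(abs(b10)), 0)
})

test_that("frame rendering follows the fluorescence model exactly", {
  tex <- matrix(0.5, 4, 4)
  v1 <- matrix(1, 4, 4)
  expect_equal(renderFrame(tex, v1, 0), tex)
  expect_equal(renderFrame(tex, v1, -0.07)[1, 1], 0.465)
  tex2 <- matrix(0.8, 2, 2)
  expect_equal(renderFrame(tex2, matrix(0.5, 2, 2), -0.10)[1, 1], 0.76)
  # mask limits the modulation
  msk <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  out <- renderFrame(tex2, matrix(1, 2, 2), -0.5, msk)
  expect_equal(out[1, 1], 0.4)
  expect_equal(out[2, 2], 0.8)
  expect_error(renderFrame(tex2, matrix(1, 2, 2), 1.2), "abs")
})

test_that("noise draws are seeded, unclipped and have the requested strength", {
  x <- matrix(0.5, 128, 128)
  expect_identical(addNoise(x, 0, 1), x)
  n1 <- addNoise(x, 0.03, 99)
  n2 <- addNoise(x, 0.03, 99)
  expect_identical(n1, n2)
  expect_lt(abs(sd(n1 - x) - 0.03) / 0.03, 0.05)
  # not clipped: strong noise must produce values outside [0, 1]
  big <- addNoise(matrix(0.02, 64, 64), 0.2, 5)
  expect_true(any(big < 0))
})

test_that("image pairs carry exact analytic ground truth", {
  # no deformation, no fluorescence, no noise: A == B, u == 0
  sc0 <- syntheticScene(width = 48L, height = 48L,
                        wave = waveModel(period = 60, upstroke = 3, decay = 12),
                        deformation = deformationModel(amplitude = 0),
                        f = 0, sigma = 0, duration = 90L, seed = 2)
  p0 <- makePair(sc0, 3, 40)
  expect_equal(p0$A, p0$B, tolerance = 1e-12)
  expect_true(all(p0$u == 0))
  # round trip on the default scene: sampling B at x + u reproduces the
  # rendered frame at t2
  sc <- syntheticScene(f = -0.05, sigma = 0)
  p <- makePair(sc, 30, 120)
  expect_lte(max(sqrt(p$u[, , 1]^2 + p$u[, , 2]^2)),
             2 * sc@deformation@amplitude)
  i2 <- renderFrame(sc@texture, waveField(sc@wave, 120, c(128L, 128L)), sc@f,
                    sc@mask)
  rec <- warpFrame(p$B, p$u)
  expect_lt(mean(abs(rec - i2)), 1e-2)
  expect_error(makePair(sc, 5, 5), "differ")
  expect_error(makePair(sc, 0, 400), "duration")
})

test_that("datasets are reproducible with distinct per-pair draws", {
  sc <- small_scene(f = -0.03, sigma = 0.02)
  d1 <- makeDataset(sc, 5, seed = 3)
  d2 <- makeDataset(sc, 5, seed = 3)
  expect_identical(d1, d2)
  times <- sapply(d1, function(p) paste(p$t1, p$t2))
  expect_gt(length(unique(times)), 1)
  expect_true(all(sapply(d1, function(p) p$t1 != p$t2)))
  # noise differs between pairs (derived seeds) and from the clean render
  expect_false(identical(d1[[1]]$A, d1[[2]]$A))
  # nonzero amplitude -> nonzero pair-averaged displacement
  expect_gt(mean(sapply(d1, function(p) mean(abs(p$u)))), 0)
  d3 <- makeDataset(sc, 5, seed = 4)
  expect_false(identical(d1[[1]]$t1, d3[[1]]$t1) &&
               identical(d1[[2]]$t1, d3[[2]]$t1) &&
               identical(d1[[3]]$t1, d3[[3]]$t1))
})

test_that("synthetic videos ship one truth field per frame, zero at the reference", {
  sc <- small_scene(f = -0.04)
  mv <- makeVideo(sc, 12)
  expect_equal(nFrames(mv$video), 12)
  expect_equal(nFrames(mv$flow), 12)
  expect_true(all(getField(mv$flow, 1) == 0))
  expect_gt(max(abs(flowFields(mv$flow))), 0)
  # static scene: all frames identical, truth zero
  sc0 <- syntheticScene(width = 32L, height = 32L,
                        wave = waveModel(period = 60, upstroke = 3, decay = 12),
                        deformation = deformationModel(amplitude = 0),
                        f = 0, sigma = 0, duration = 60L, seed = 2)
  mv0 <- makeVideo(sc0, 5)
  for (t in 2:5) expect_equal(getFrame(mv0$video, t), getFrame(mv0$video, 1))
  expect_true(all(flowFields(mv0$flow) == 0))
})

test_that("scene validity bounds fluorescence, noise and texture", {
  expect_error(syntheticScene(f = -0.7), "0.5")
  expect_error(syntheticScene(sigma = -1), "sigma")
})
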