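test_that("the normalization window length follows the frame interval", {
  # 20 ms at 500 fps (2 ms interval) -> 10 frames
  expect_equal(normWindowFrames(20, 2), 10L)
  expect_equal(normWindowFrames(0.5, 2), 2L)  # floor of 2 frames
  expect_equal(normWindowFrames(6000, 25), 240L)
})

test_that("pixel-wise normalization matches the brute-force windowed scan", {
  set.seed(12)
  arr <- array(runif(6 * 5 * 12), c(6, 5, 12))
  v <- videoStack(arr, frameIntervalMs = 2)
  for (win_ms in c(8, 20)) {
    L <- normWindowFrames(win_ms, 2)
    got <- frames(pixelwiseNormalize(v, win_ms))
    expect_equal(got, oracle_window_norm(arr, L), tolerance = 1e-12)
  }
  # sawtooth trace, L = 4
  saw <- array(rep(c(1, 2, 3, 4), 3), c(1, 1, 12))
  got <- frames(pixelwiseNormalize(videoStack(saw, frameIntervalMs = 1), 4))
  expect_equal(got, oracle_window_norm(saw, 4), tolerance = 1e-12)
})

test_that("normalization output is in [0,1], flat-guarded and affine-invariant", {
  set.seed(13)
  arr <- array(runif(4 * 4 * 20), c(4, 4, 20))
  v <- videoStack(arr, frameIntervalMs = 2)
  n1 <- frames(pixelwiseNormalize(v, 10))
  expect_true(all(n1 >= 0 & n1 <= 1))
  n2 <- frames(pixelwiseNormalize(videoStack(3 * arr + 1, frameIntervalMs = 2), 10))
  expect_equal(n2, n1, tolerance = 1e-9)
  const <- videoStack(array(0.3, c(3, 3, 8)), frameIntervalMs = 2)
  expect_true(all(frames(pixelwiseNormalize(const, 10)) == 0))
  expect_error(pixelwiseNormalize(v, -1), "windowMs")
})

test_that("ROI traces equal direct box means and clip at image borders", {
  set.seed(14)
  arr <- array(runif(20 * 20 * 5), c(20, 20, 5))
  v <- videoStack(arr, frameIntervalMs = 2)
  r <- roi(10, 8, 6L)
  tr <- extractTrace(v, r)
  # direct 36-pixel mean: box rows 6..11, cols 8..13 (size-6 box at (10, 8))
  direct <- apply(arr[6:11, 8:13, ], 3, mean)
  expect_equal(tr, direct, tolerance = 1e-12)
  # 1x1 ROI is the pixel time course
  expect_equal(extractTrace(v, roi(4, 7, 1L)), arr[7, 4, ])
  # constant stack -> constant trace
  cv <- videoStack(array(0.2, c(8, 8, 3)), frameIntervalMs = 2)
  expect_equal(extractTrace(cv, roi(4, 4)), rep(0.2, 3))
  # border clipping keeps the trace defined
  expect_length(extractTrace(v, roi(1, 1, 6L)), 5)
  expect_error(extractTrace(v, roi(80, 80, 6L)), "outside")
})

test_that("EPE matches the loop oracle and behaves like a metric aggregate", {
  est <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  tru <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  expect_equal(computeEPE(est, tru), oracle_epe(est, tru), tolerance = 1e-12)
  set.seed(15)
  mask <- matrix(runif(64) > 0.5, 8, 8)
  expect_equal(computeEPE(est, tru, mask), oracle_epe(est, tru, mask),
               tolerance = 1e-12)
  # exact zero on equality; 3-4-5 offset; symmetry; translation invariance
  expect_equal(computeEPE(tru, tru), 0)
  off <- tru
  off[, , 1] <- off[, , 1] + 3
  off[, , 2] <- off[, , 2] + 4
  expect_equal(computeEPE(off, tru), 5)
  expect_equal(computeEPE(est, tru), computeEPE(tru, est))
  expect_equal(computeEPE(est + 2, tru + 2), computeEPE(est, tru),
               tolerance = 1e-12)
  expect_error(computeEPE(est, array(0, c(4, 4, 2))), "shape")
})
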