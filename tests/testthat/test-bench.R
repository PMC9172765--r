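test_that("fluorescence sweeps produce one record per cell and round-trip CSV", {
  sc <- small_scene()
  rec <- sweepFluorescence(c("lucas_kanade", "farneback"), c(0, 5),
                           ceModes = c(FALSE, TRUE), scene = sc, nPairs = 3,
                           seed = 2, ceKernel = 5L)
  expect_equal(nrow(rec), 2 * 2 * 2)
  expect_true(all(rec$mean_epe_px >= 0 & is.finite(rec$mean_epe_px)))
  expect_true(all(rec$n_pairs == 3))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  writeReport(rec, tmp)
  back <- read.csv(tmp)
  expect_equal(names(back)[1:7],
               c("backend", "f_percent", "sigma", "contrast_enhanced",
                 "mean_epe_px", "n_pairs", "seconds_per_pair"))
  expect_equal(back$mean_epe_px, rec$mean_epe_px, tolerance = 1e-9)
  expect_equal(nrow(back), 8)
  # empty record list -> header-only file
  writeReport(rec[0, ], tmp)
  expect_length(readLines(tmp), 1)
  # 3 records -> 4-line file
  writeReport(rec[1:3, ], tmp)
  expect_length(readLines(tmp), 4)
})

test_that("the sigma = 0 noise-sweep row equals the fluorescence-sweep cell", {
  sc <- small_scene()
  rf <- sweepFluorescence("farneback", 3, ceModes = FALSE, scene = sc,
                          nPairs = 4, seed = 7, ceKernel = 5L)
  rn <- sweepNoise("farneback", c(0, 0.05), scene = sc, f = 3, nPairs = 4,
                   seed = 7, ceKernel = 5L)
  expect_equal(rn$mean_epe_px[rn$sigma == 0], rf$mean_epe_px, tolerance = 1e-12)
  expect_equal(nrow(rn), 2)
})

test_that("full sweeps are reproducible under a fixed master seed", {
  sc <- small_scene()
  r1 <- sweepNoise("lucas_kanade", c(0, 0.03), scene = sc, nPairs = 3, seed = 5)
  r2 <- sweepNoise("lucas_kanade", c(0, 0.03), scene = sc, nPairs = 3, seed = 5)
  expect_equal(r1$mean_epe_px, r2$mean_epe_px, tolerance = 1e-12)
})

test_that("the harness computes EPE on unsmoothed fields", {
  # benchmarkBackend must reproduce the per-pair EPE of the raw estimate;
  # smoothing the field first would change it
  sc <- small_scene()
  ds <- makeDataset(sc, 2, seed = 9)
  epes <- benchmarkBackend(ds, "lucas_kanade")
  manual <- sapply(ds, function(p) {
    est <- estimateFlowPair(p$A, p$B, backend = "lucas_kanade")
    computeEPE(est, p$u)
  })
  expect_equal(as.numeric(epes), as.numeric(manual), tolerance = 1e-12)
  # and a smoothed version really is different (guards the wiring)
  p <- ds[[1]]
  est <- estimateFlowPair(p$A, p$B, backend = "lucas_kanade")
  fields <- array(0, c(dim(est)[1:2], 2, 2))
  fields[, , , 2] <- est
  smoothed <- getField(smoothFlow(flowSequence(fields, 1L), 3, 3, 1), 2)
  expect_false(isTRUE(all.equal(computeEPE(smoothed, p$u), epes[1],
                                tolerance = 1e-12)))
})

test_that("speed measurements report positive steady-state rates", {
  res <- measureSpeed("lucas_kanade", imageSize = 48L, nFrames = 10L)
  expect_gt(res$fps, 0)
  expect_gt(res$ms_per_pair, 0)
  expect_true(is.finite(res$ms_sd))
  expect_equal(res$n, 10)
  expect_false(res$include_prepost)
})
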