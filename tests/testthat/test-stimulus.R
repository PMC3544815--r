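test_that("drifting gratings honor contrast, frame count and luminance", {
  # zero contrast: every frame uniformly at the mean
  g0 <- makeDriftingGrating(2, 0.058, contrast = 0, meanLuminance = 1.7,
                            duration = 1)
  expect_equal(nFrames(g0), 15)
  expect_true(all(frames(g0) == 1.7))

  # full contrast with grid-aligned phases: min 0, max 2*mean exactly
  g1 <- makeDriftingGrating(3.75, 0.0625, contrast = 1, meanLuminance = 2,
                            duration = 2, width = 16, degPerPixel = 2)
  expect_equal(min(frames(g1)), 0, tolerance = 1e-12)
  expect_equal(max(frames(g1)), 4, tolerance = 1e-12)

  # whole temporal cycles conserve the mean
  g2 <- makeDriftingGrating(3, 0.058, contrast = 1, meanLuminance = 1.7,
                            duration = 1)
  expect_equal(mean(frames(g2)), 1.7, tolerance = 1e-10)

  expect_error(makeDriftingGrating(2, 0.26, degPerPixel = 2),
               "Nyquist")
})

test_that("binary white noise has the stated moments and is seeded", {
  wn <- makeBinaryWhiteNoise(1, 0.16, duration = 200, width = 16,
                             height = 16, seed = 4)
  expect_true(all(frames(wn) %in% c(0.84, 1.16)))
  expect_equal(mean(frames(wn)), 1, tolerance = 0.01)       # binomial s.e. ~2e-4
  expect_equal(sd(as.vector(frames(wn))), 0.16, tolerance = 0.01)
  wn2 <- makeBinaryWhiteNoise(1, 0.16, duration = 200, width = 16,
                              height = 16, seed = 4)
  expect_identical(frames(wn), frames(wn2))
  expect_error(makeBinaryWhiteNoise(1, 1.5, duration = 1), "amplitude")
})

test_that("natural movies are seeded, clip-guarded, and flat at zero exponents", {
  nm <- makeNaturalMovie(duration = 10, width = 16, height = 16, seed = 5)
  nm2 <- makeNaturalMovie(duration = 10, width = 16, height = 16, seed = 5)
  expect_identical(frames(nm), frames(nm2))
  expect_equal(mean(frames(nm)), 1, tolerance = 0.01)
  expect_warning(
    makeNaturalMovie(duration = 10, width = 16, height = 16,
                     rmsContrast = 0.9, seed = 5),
    "clips")
  flat <- makeNaturalMovie(temporalExponent = 0, spatialExponent = 0,
                           duration = 256 / 15, width = 16, height = 16,
                           seed = 6)
  expect_lt(abs(estimateSpectrumExponent(flat, "time")), 0.1)
})

test_that("assembled streams partition frames into labeled segments and gray", {
  segs <- lapply(1:30, function(i) makeGray(1, duration = 1, width = 8,
                                            height = 8))
  names(segs) <- sprintf("seg%02d", 1:30)
  ens <- stimulusEnsemble(segs)
  expect_equal(nStim(ens), 30)
  expect_equal(stimulusEntropy(ens), log2(30))

  st <- assembleStream(ens)
  expect_equal(length(stimLabels(st)), 30 * 15 + 30 * 5)   # 600 frames/repeat
  # every frame has exactly one label; non-gray runs reproduce the order
  runs <- rle(stimLabels(st))
  expect_identical(runs$values[runs$values != "GRAY"], names(segs))
  expect_true(all(runs$lengths[runs$values == "GRAY"] == 5))

  empty <- assembleStream(ens, order = character(0))
  expect_equal(nFrames(empty@movie), 0)
  expect_identical(stimLabels(empty), character(0))

  expect_error(assembleStream(ens, order = "nope"), "unknown")
})

test_that("grating/gray streams conserve mean luminance", {
  segs <- lapply(c(1, 3, 5), function(f)
    makeDriftingGrating(f, 0.058, contrast = 1, meanLuminance = 1.7,
                        duration = 1, width = 8, height = 8))
  names(segs) <- sprintf("tf%d", c(1, 3, 5))
  st <- assembleStream(stimulusEnsemble(segs))
  expect_equal(mean(frames(st@movie)), 1.7, tolerance = 0.01)
})
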