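test_that("populations honor the polarity mix, geometry and seed", {
  pop <- makePopulation(20, fracOn = 0.5, seed = 91)
  pol <- vapply(pop, function(cc) cc@polarity, character(1))
  expect_equal(sum(pol == "ON"), 10)
  expect_equal(sum(pol == "OFF"), 10)
  expect_true(all(vapply(pop, function(cc)
    identical(dim(cc@spatialWeights), c(10L, 10L)), logical(1))))
  # ON centers positive, OFF centers negative
  ctrSign <- vapply(pop, function(cc) sign(cc@spatialWeights[5, 5]),
                    numeric(1))
  expect_true(all(ctrSign[pol == "ON"] > 0) && all(ctrSign[pol == "OFF"] < 0))

  pop2 <- makePopulation(20, fracOn = 0.5, seed = 91)
  expect_equal(pop, pop2)
  # scotopic preset is slower: later temporal energy than photopic
  sco <- makePopulation(6, condition = "scotopic", seed = 92)
  pho <- makePopulation(6, condition = "photopic", seed = 92)
  latency <- function(cells) vapply(cells, function(cc) {
    f <- temporalFilter(cc)
    tt <- (seq_along(f) - 0.5) * cc@basis@binWidth
    sum(tt * f^2) / sum(f^2)
  }, numeric(1))
  expect_true(all(latency(sco) > latency(pho)))     # paired draws, same seed
})

test_that("cells and rasters round-trip their serialization formats", {
  pop <- makePopulation(2, seed = 93)
  f <- tempfile(fileext = ".json")
  writeCellJSON(pop[[1]], f)
  back <- readCellJSON(f)
  expect_equal(back@spatialWeights, pop[[1]]@spatialWeights)
  expect_equal(back@temporalCoeffs, pop[[1]]@temporalCoeffs)
  expect_equal(back@basis@basis, pop[[1]]@basis@basis)
  expect_identical(back@polarity, pop[[1]]@polarity)
  expect_identical(back@rfCenter, pop[[1]]@rfCenter)
  expect_equal(back@nonlinearity@offset, pop[[1]]@nonlinearity@offset)
  # spline nonlinearity round-trips too
  sp <- lnpCell(matrix(1, 10, 10), rep(1, 10),
                splineNonlinearity(-3:3, c(1, 2, 4, 8, 16, 32, 64)))
  writeCellJSON(sp, f)
  expect_equal(readCellJSON(f)@nonlinearity@values,
               sp@nonlinearity@values)

  r <- sampleSpikes(rep(15, 60), nTrials = 3, binWidth = 1/15, seed = 94,
                    cellId = "roundtrip")
  g <- tempfile(fileext = ".csv")
  writeRasterCSV(r, g)
  back <- readRasterCSV(g)
  expect_equal(back@trials, r@trials)
  expect_equal(back@duration, r@duration)
  expect_identical(back@cellId, r@cellId)
  unlink(c(f, g))
})

test_that("module seeds are stable hashes below 2^31", {
  expect_identical(moduleSeed(1, "population"), moduleSeed(1, "population"))
  expect_false(moduleSeed(1, "population") == moduleSeed(2, "population"))
  expect_false(moduleSeed(1, "population") == moduleSeed(1, "spikes"))
  s <- vapply(letters, function(m) moduleSeed(123456, m), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
})

test_that("a small recovery pipeline is byte-reproducible under one seed", {
  r1 <- runRecovery(nCells = 1, trainMinutes = 3, testMinutes = 1,
                    evaluate = FALSE, seed = 5)
  r2 <- runRecovery(nCells = 1, trainMinutes = 3, testMinutes = 1,
                    evaluate = FALSE, seed = 5)
  expect_identical(r1$filterCorr, r2$filterCorr)
  expect_identical(r1$heldOutCorr, r2$heldOutCorr)
  expect_equal(r1$fits[[1]]@zTrajectory, r2$fits[[1]]@zTrajectory)
})
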