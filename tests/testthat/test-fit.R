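test_that("log-likelihood matches the binned Poisson formula", {
  b <- raisedCosineBasis()
  # constant-rate cell: zero filter drive, exp(offset) = 10 sp/s
  cell <- lnpCell(matrix(1e-12, 10, 10), rep(1, 10),
                  exponentialNonlinearity(gain = 1, offset = log(10)),
                  basis = b)
  mov <- makeGray(0, duration = 20 / 15, width = 10, height = 10)
  dt <- 1 / 15
  tValid <- 3 * dt                                # frames 18..20 are valid
  # one spike in a valid bin
  r1 <- new("SpikeRaster", trials = list(18.5 * dt), duration = 20 * dt,
            cellId = "c")
  expect_equal(as.numeric(logLikelihoodLNP(cell, mov, r1)),
               log(10) - 10 * tValid, tolerance = 1e-10)
  # no spikes anywhere: Z = -lambda * T
  r0 <- new("SpikeRaster", trials = list(numeric(0)), duration = 20 * dt,
            cellId = "c")
  expect_equal(as.numeric(logLikelihoodLNP(cell, mov, r0)), -10 * tValid,
               tolerance = 1e-10)
  # doubling lambda changes Z by n*log(2) - lambda*T
  cell2 <- lnpCell(matrix(1e-12, 10, 10), rep(1, 10),
                   exponentialNonlinearity(gain = 1, offset = log(20)),
                   basis = b)
  expect_equal(as.numeric(logLikelihoodLNP(cell2, mov, r1)) -
                 as.numeric(logLikelihoodLNP(cell, mov, r1)),
               log(2) - 10 * tValid, tolerance = 1e-10)
  # warm-up spikes are excluded and counted
  rw <- new("SpikeRaster", trials = list(c(0.5 * dt, 18.5 * dt)),
            duration = 20 * dt, cellId = "c")
  expect_equal(attr(logLikelihoodLNP(cell, mov, rw), "excludedSpikes"), 1)
})

test_that("knots cover the generator-signal range evenly", {
  expect_equal(placeKnots(c(-3, 3)), -3:3)
  k <- placeKnots(rnorm(100))
  expect_length(k, 7)
  expect_false(is.unsorted(k))
  expect_error(placeKnots(rep(1, 50)), "degenerate")
})

test_that("exponential-stage fitting recovers a known cell from white noise", {
  pop <- makePopulation(1, fracOn = 1, seed = 31)
  cell <- pop[[1]]
  train <- makeBinaryWhiteNoise(1, 0.16, duration = 240, width = 16,
                                height = 16, seed = 32)
  lam <- firingRate(cell, train)
  raster <- sampleSpikes(lam, 1, 1/15, seed = 33)
  fit <- fitLNP(train, raster, basis = cell@basis,
                config = fitConfig(useSpline = FALSE))
  truthF <- as.vector(retinaLNP:::embedFilter(cell, c(16L, 16L)))
  fitF <- as.vector(retinaLNP:::embedFilter(fittedCell(fit), c(16L, 16L)))
  expect_gt(abs(cor(truthF, fitF)), 0.9)
  # ascent contract: final Z at least the initialization Z
  expect_gte(fit@zTrajectory[length(fit@zTrajectory)], fit@zTrajectory[1])
  # temporal coefficients normalized to unit norm (identifiability)
  expect_equal(sum(fittedCell(fit)@temporalCoeffs^2), 1, tolerance = 1e-8)
})

test_that("the exponential likelihood has one maximum: restarts agree", {
  pop <- makePopulation(1, fracOn = 1, seed = 41)
  cell <- pop[[1]]
  train <- makeBinaryWhiteNoise(1, 0.16, duration = 180, width = 16,
                                height = 16, seed = 42)
  raster <- sampleSpikes(firingRate(cell, train), 1, 1/15, seed = 43)
  zEnd <- vapply(c(101, 202), function(s) {
    f <- fitLNP(train, raster, basis = cell@basis,
                config = fitConfig(useSpline = FALSE, init = "random",
                                   seed = s, stage1MaxIters = 40))
    f@zTrajectory[length(f@zTrajectory)]
  }, numeric(1))
  nspk <- length(raster@trials[[1]])
  expect_lt(abs(diff(zEnd)) / nspk, 1e-4)
})

test_that("the spline stage ascends and refit is scale-invariant", {
  pop <- makePopulation(1, fracOn = 1, seed = 51)
  cell <- pop[[1]]
  train <- makeBinaryWhiteNoise(1, 0.16, duration = 240, width = 16,
                                height = 16, seed = 52)
  raster <- sampleSpikes(firingRate(cell, train), 1, 1/15, seed = 53)
  fit <- fitLNP(train, raster, basis = cell@basis,
                config = fitConfig(maxOuterIters = 15))
  z <- fit@zTrajectory
  # monotone within each stage (the exp->spline swap may step once)
  stageDiffs <- diff(z)[-(fit@splineStageAt - 1L)]
  expect_true(all(stageDiffs >= -1e-6 * abs(z[1])))
  expect_equal(sum(fittedCell(fit)@temporalCoeffs^2), 1, tolerance = 1e-8)

  # spatial/temporal scale swap on the truth leaves the fitted filters the
  # same after normalization: refit from identical data must reproduce them
  fit2 <- fitLNP(train, raster, basis = cell@basis,
                 config = fitConfig(maxOuterIters = 15))
  expect_equal(fittedCell(fit)@temporalCoeffs, fittedCell(fit2)@temporalCoeffs)
  expect_equal(fittedCell(fit)@spatialWeights, fittedCell(fit2)@spatialWeights)
})
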