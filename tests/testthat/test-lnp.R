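test_that("raised-cosine basis has the stated shape and properties", {
  b <- raisedCosineBasis()
  expect_equal(dim(b@basis), c(10L, 18L))
  expect_true(all(b@basis >= 0 & b@basis <= 1))
  expect_equal(unname(apply(b@basis, 1, max)), rep(1, 10))
  expect_equal(qr(b@basis)$rank, 10L)          # rows linearly independent
  # each basis function rises to a single maximum and falls
  unimodal <- apply(b@basis, 1, function(r) {
    p <- which.max(r)
    all(diff(r[seq_len(p)]) >= 0) && all(diff(r[p:length(r)]) <= 0)
  })
  expect_true(all(unimodal))
  # unit coefficient vector reproduces basis function j as the filter
  for (j in c(1, 5, 10)) {
    cc <- lnpCell(matrix(1, 10, 10), as.numeric(seq_len(10) == j), basis = b)
    expect_equal(temporalFilter(cc), b@basis[j, ])
  }
})

test_that("linear drive is a causal spatiotemporal convolution", {
  b <- raisedCosineBasis()
  set.seed(21)
  w <- matrix(rnorm(100), 10, 10)
  a <- rnorm(10)
  cell <- lnpCell(w, a, basis = b)
  zero <- makeGray(0, duration = 3, width = 10, height = 10)
  gz <- linearDrive(cell, zero)
  expect_equal(sum(is.na(gz)), 17)             # warm-up marked, not padded
  expect_true(all(gz[!is.na(gz)] == 0))

  # impulse at one pixel reproduces spatial weight times temporal filter
  fr <- array(0, c(45, 10, 10))
  fr[20, 3, 7] <- 1
  imp <- new("StimulusMovie", frames = fr, frameRate = 15, degPerPixel = 2.16,
             meanLuminance = 0, rmsContrast = 0)
  g <- linearDrive(cell, imp)
  f <- temporalFilter(cell)
  expect_equal(g[20:37], w[3, 7] * f, tolerance = 1e-12)

  # linearity in the stimulus
  m1 <- makeBinaryWhiteNoise(1, 0.3, duration = 3, width = 10, height = 10,
                             seed = 22)
  m2 <- makeBinaryWhiteNoise(1, 0.3, duration = 3, width = 10, height = 10,
                             seed = 23)
  comb <- new("StimulusMovie",
              frames = 2 * frames(m1) + 3 * frames(m2),
              frameRate = 15, degPerPixel = 2.16, meanLuminance = 5,
              rmsContrast = 1)
  g12 <- linearDrive(cell, comb)
  gl <- 2 * linearDrive(cell, m1) + 3 * linearDrive(cell, m2)
  expect_equal(g12, gl, tolerance = 1e-9)

  # patch outside the movie
  off <- lnpCell(w, a, rfCenter = c(2, 2), basis = b)
  expect_error(linearDrive(off, m1), "outside")
})

test_that("rate respects the nonlinearity, the floor, and balanced surrounds", {
  b <- raisedCosineBasis()
  cell <- lnpCell(matrix(1, 10, 10), rep(1, 10),
                  exponentialNonlinearity(gain = 3, offset = 0), basis = b)
  zero <- makeGray(0, duration = 2, width = 10, height = 10)
  lam <- firingRate(cell, zero)
  expect_equal(unique(lam[!is.na(lam)]), 1)     # exp(0) = 1 spike/s

  # clamped at the rate floor
  low <- lnpCell(matrix(1, 10, 10), rep(1, 10),
                 exponentialNonlinearity(gain = 0, offset = -50,
                                         rateFloor = 1e-3), basis = b)
  lamLow <- firingRate(low, zero)
  expect_equal(unique(lamLow[!is.na(lamLow)]), 1e-3)

  # spline nonlinearity passes through its knot values
  nl <- splineNonlinearity(-3:3, c(0.5, 1, 2, 4, 8, 16, 32))
  expect_equal(evalNonlinearity(nl, -3:3), c(0.5, 1, 2, 4, 8, 16, 32))

  # zero-sum spatial weights make the rate invariant to a luminance offset
  set.seed(24)
  w <- matrix(rnorm(100), 10, 10); w <- w - mean(w)
  bal <- lnpCell(w, rnorm(10), basis = b)
  m <- makeBinaryWhiteNoise(1, 0.2, duration = 3, width = 10, height = 10,
                            seed = 25)
  mShift <- new("StimulusMovie", frames = frames(m) + 0.7, frameRate = 15,
                degPerPixel = 2.16, meanLuminance = 1.7, rmsContrast = 0.2)
  expect_equal(firingRate(bal, m), firingRate(bal, mShift), tolerance = 1e-9)

  # doubling the contrast doubles the generator signal exactly
  mDouble <- new("StimulusMovie", frames = 1 + 2 * (frames(m) - 1),
                 frameRate = 15, degPerPixel = 2.16, meanLuminance = 1,
                 rmsContrast = 0.4)
  expect_equal(linearDrive(bal, mDouble), 2 * linearDrive(bal, m),
               tolerance = 1e-9)
})

test_that("spike sampling matches Poisson statistics and is reproducible", {
  r0 <- sampleSpikes(rep(0, 30), nTrials = 5, binWidth = 1/15, seed = 1)
  expect_true(all(vapply(r0@trials, length, integer(1)) == 0))

  r1 <- sampleSpikes(rep(20, 75), nTrials = 200, binWidth = 1/15, seed = 2)
  n <- vapply(r1@trials, length, integer(1))
  expect_equal(mean(n), 100, tolerance = 3 * sqrt(100 / 200) / 100)
  expect_equal(var(n) / mean(n), 1, tolerance = 0.25)       # Fano ~ 1

  r2 <- sampleSpikes(rep(20, 75), nTrials = 200, binWidth = 1/15, seed = 2)
  expect_identical(r1@trials, r2@trials)

  # PSTH converges to lambda * dt
  lam <- c(rep(5, 30), rep(40, 30))
  rr <- sampleSpikes(lam, nTrials = 400, binWidth = 1/15, seed = 3)
  cm <- retinaLNP:::frameCounts(rr, 60, 15)
  psth <- colMeans(cm)
  expect_equal(mean(psth[1:30]), 5 / 15, tolerance = 0.1)
  expect_equal(mean(psth[31:60]), 40 / 15, tolerance = 0.05)
})
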