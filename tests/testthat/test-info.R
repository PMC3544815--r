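test_that("response log-probabilities match the Poisson pmf", {
  expect_equal(responseLogProb(0, 1), -1)
  expect_equal(responseLogProb(c(0, 0), c(1, 2)), -3)
  expect_equal(responseLogProb(2, 0.5), 2 * log(0.5) - 0.5 - log(2))
  expect_error(responseLogProb(-1, 1), "non-negative")
  # zero intensities floored, not -Inf
  expect_true(is.finite(responseLogProb(c(1, 0), c(0, 2))))
})

test_that("binned counts follow the half-open convention and conserve spikes", {
  segs <- lapply(1:2, function(i) makeGray(1, duration = 1, width = 8,
                                           height = 8))
  names(segs) <- c("A", "B")
  st <- assembleStream(stimulusEnsemble(segs))
  # stream: A at [0,1), gray [1,1.333), B at [1.333,2.333), gray...
  r <- new("SpikeRaster",
           trials = list(c(0.10, 0.25, 1.1, 1.4)), duration = 40 / 15,
           cellId = "c")
  bn <- binCounts(r, st, binWidth = 0.25)
  expect_equal(as.vector(counts(bn)[1, "A", ]), c(1, 1, 0, 0))
  # the 1.1 s spike (gray) is excluded; 1.4 s falls in segment B bin 1
  expect_equal(sum(counts(bn)[1, "B", ]), 1)
  expect_equal(sum(counts(bn)), 3)

  empty <- new("SpikeRaster", trials = list(numeric(0)), duration = 40 / 15,
               cellId = "c")
  expect_true(all(counts(binCounts(empty, st, 0.25)) == 0))

  expect_error(binCounts(r, st, binWidth = 0.3), "divide")
})

test_that("rate profiles are trial means", {
  cnt <- array(0L, c(2, 1, 1), dimnames = list(NULL, "A", NULL))
  cnt[1, 1, 1] <- 2L; cnt[2, 1, 1] <- 4L
  bn <- new("BinnedResponse", counts = cnt, binWidth = 0.25,
            trialIds = 1:2, sourceId = "")
  expect_equal(as.vector(profileMatrix(rateProfiles(bn))), 3)
  # duplicating trials leaves the mean unchanged
  bn2 <- new("BinnedResponse", counts = cnt[c(1, 2, 1, 2), , , drop = FALSE],
             binWidth = 0.25, trialIds = 1:4, sourceId = "")
  expect_equal(profileMatrix(rateProfiles(bn2)),
               profileMatrix(rateProfiles(bn)))
})

test_that("Poisson MI: zero for uninformative profiles, bounded by entropy", {
  uSame <- matrix(rep(c(0.5, 1.2), each = 8), 8, 2)
  miSame <- mutualInformationPoisson(mkProfiles(uSame), mcSamples = 5000,
                                     seed = 1, method = "mc")
  expect_lt(abs(miValue(miSame)), 3 * miSame@se + 1e-12)

  set.seed(61)
  for (rep in 1:10) {
    nS <- sample(2:5, 1)
    u <- matrix(runif(nS * 2, 0, 4), nS, 2)
    mi <- mutualInformationPoisson(mkProfiles(u), method = "exact")
    expect_gte(miValue(mi), 0)
    expect_lte(miValue(mi), log2(nS) + 1e-9)
  }
})

test_that("Monte-Carlo MI is unbiased against exact enumeration", {
  u <- matrix(c(0.01, 8), 2, 1)
  ex <- mutualInformationPoisson(mkProfiles(u), method = "exact")
  mc <- mutualInformationPoisson(mkProfiles(u), method = "mc",
                                 mcSamples = 50000, seed = 2)
  expect_lt(abs(miValue(mc) - miValue(ex)), 3 * mc@se)
  expect_warning(
    mutualInformationPoisson(mkProfiles(u), method = "mc", mcSamples = 500,
                             seed = 3),
    "1000")
})

test_that("merging stimuli never increases information (data processing)", {
  # exact enumeration oracle, including the merged mixture conditionals
  set.seed(62)
  for (rep in 1:5) {
    u <- matrix(runif(3 * 2, 0, 4), 3, 2)
    iOrig <- miValue(mutualInformationPoisson(mkProfiles(u), method = "exact"))
    cap <- max(qpois(1 - 1e-9, max(u)), 5)
    grid <- as.matrix(expand.grid(0:cap, 0:cap))
    pr <- function(s) dpois(grid[, 1], u[s, 1]) * dpois(grid[, 2], u[s, 2])
    pm <- cbind((pr(1) + pr(2)) / 2, pr(3))     # merge stimuli 1 and 2
    prior <- c(2/3, 1/3)
    marg <- pm %*% prior
    term <- pm * log2(pm / as.vector(marg))
    term[!is.finite(term)] <- 0
    iMerged <- sum(sweep(term, 2, prior, `*`))
    expect_lte(iMerged, iOrig + 1e-9)
  }
})

test_that("quartile MI: exact for noiseless codes, zero for silence", {
  # 4 stimuli with deterministic levels, distinct in one bin -> log2(4) bits
  cnt <- array(0L, c(6, 4, 2), dimnames = list(NULL, paste0("s", 1:4), NULL))
  pat <- rbind(c(0, 1), c(1, 1), c(2, 1), c(3, 1))
  for (s in 1:4) cnt[, s, ] <- rep(pat[s, ], each = 6)
  bn <- new("BinnedResponse", counts = cnt, binWidth = 0.25, trialIds = 1:6,
            sourceId = "")
  expect_equal(miValue(mutualInformationQuartile(bn, debias = FALSE)), 2)

  zero <- new("BinnedResponse",
              counts = array(0L, c(6, 4, 2),
                             dimnames = list(NULL, paste0("s", 1:4), NULL)),
              binWidth = 0.25, trialIds = 1:6, sourceId = "")
  expect_equal(miValue(mutualInformationQuartile(zero, debias = FALSE)), 0)
  expect_error(mutualInformationQuartile(
    new("BinnedResponse", counts = cnt[1, , , drop = FALSE],
        binWidth = 0.25, trialIds = 1L, sourceId = "")), "2 trials")
})

test_that("quadratic extrapolation recovers exact quadratics", {
  x <- c(0.1, 0.2, 0.4)
  expect_equal(debiasQuadratic(1 / x, 2 + x + 0.5 * x^2, nTrials = 1), 2,
               tolerance = 1e-10)
  expect_equal(debiasQuadratic(c(1, 0.5, 0.25), rep(3.3, 3), nTrials = 40),
               3.3, tolerance = 1e-10)
  expect_error(debiasQuadratic(c(1, 0.5), c(1, 2)), "3 distinct")
})

test_that("debiasing removes the positive plug-in bias on Poisson data", {
  set.seed(63)
  u <- matrix(rgamma(10 * 8, shape = 1.2, rate = 4), 10, 8)
  bn <- simulateBinnedResponse(mkProfiles(u, binWidth = 1/8), 60, seed = 64)
  plugin <- miValue(mutualInformationQuartile(bn, debias = FALSE))
  deb <- miValue(mutualInformationQuartile(bn, seed = 65))
  expect_lte(deb, plugin)
})
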