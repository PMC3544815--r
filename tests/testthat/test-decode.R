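test_that("posterior matrices follow Bayes' rule and normalize", {
  # hand-computed two-stimulus case: u = (1, 2), observed count 0
  u <- matrix(c(1, 2), 2, 1, dimnames = list(c("a", "b"), NULL))
  prof <- mkProfiles(u, sourceId = "x")
  cnt <- array(0L, c(1, 2, 1), dimnames = list(NULL, c("a", "b"), NULL))
  test <- new("BinnedResponse", counts = cnt, binWidth = 0.25,
              trialIds = 5L, sourceId = "y")
  Q <- posterior(posteriorMatrix(prof, test))
  expect_equal(Q[1, ], c(a = exp(-1), b = exp(-2)) / (exp(-1) + exp(-2)),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(Q)), c(1, 1), tolerance = 1e-12)

  # identical profiles across stimuli: every row uniform
  uS <- matrix(1, 4, 2)
  profS <- mkProfiles(uS)
  testS <- simulateBinnedResponse(mkProfiles(uS), 10, seed = 1,
                                  sourceId = "other")
  QS <- posterior(posteriorMatrix(profS, testS))
  expect_true(all(abs(QS - 0.25) < 1e-9))

  # near-noiseless, perfectly discriminating profiles: identity matrix
  uD <- matrix(1e-4, 5, 5) + diag(5) * 60
  dimnames(uD) <- list(paste0("s", 1:5), NULL)
  profD <- mkProfiles(uD)
  testD <- simulateBinnedResponse(profD, 8, seed = 2, sourceId = "other")
  QD <- posterior(posteriorMatrix(profD, testD))
  expect_equal(unname(QD), diag(5), tolerance = 1e-4)

  # overlapping train/test trials from the same source are rejected
  trn <- simulateBinnedResponse(mkProfiles(uS, sourceId = "same"), 10,
                                seed = 3, sourceId = "same")
  expect_error(posteriorMatrix(rateProfiles(trn), trn), "overlap")
})

test_that("MSE alpha endpoints: identical rows 0, shuffled rows about 1", {
  Q <- randomPosterior(30, seed = 71)
  expect_identical(alphaValue(mseAlpha(Q, Q, nShuffles = 100, seed = 1)), 0)

  meds <- vapply(1:20, function(s) {
    set.seed(500 + s)
    Qp <- t(apply(Q, 1, function(row) row[sample.int(30)]))
    alphaValue(mseAlpha(Qp, Q, nShuffles = 100, seed = 600 + s))
  }, numeric(1))
  expect_equal(mean(meds), 1, tolerance = 0.1)

  # mismatched concentrated rows exceed 1 and are not clipped
  d <- diag(30)
  shifted <- d[c(2:30, 1), ]
  expect_gt(alphaValue(mseAlpha(shifted, d, nShuffles = 200, seed = 2)), 1)

  # identical constant rows have no shuffle scale and are excluded
  flat <- matrix(1 / 30, 30, 30)
  expect_message(a <- mseAlpha(flat, flat, nShuffles = 10, seed = 3),
                 "excluded")
  expect_true(all(is.na(a@perRow)))
  expect_true(is.na(alphaValue(a)))
})

test_that("KL alpha: regularization arithmetic and analytic reference", {
  d3 <- diag(3)
  expect_equal(alphaValue(klAlpha(d3, d3)), 0)
  # add-half on (1,0,0) at one trial gives (0.6, 0.2, 0.2)
  unif3 <- matrix(1/3, 3, 3)
  r <- c(0.6, 0.2, 0.2)
  m <- rep((1/3 + 0.5) / 2.5, 3)
  expect_equal(alphaValue(klAlpha(unif3, d3, nTrials = 1)),
               sum(r * log2(r / m)), tolerance = 1e-12)
  # unregularized delta-vs-uniform over 30 stimuli: the stimulus entropy
  expect_equal(alphaValue(klAlpha(matrix(1/30, 30, 30), diag(30),
                                  regularize = FALSE)),
               log2(30), tolerance = 1e-12)
})

test_that("JS alpha: zero, maximum 1 bit, and symmetric", {
  d <- diag(30)
  expect_equal(alphaValue(jsAlpha(d, d)), 0)
  expect_equal(alphaValue(jsAlpha(d[c(2:30, 1), ], d)), 1, tolerance = 1e-12)
  A <- randomPosterior(10, seed = 72)
  B <- randomPosterior(10, seed = 73)
  expect_equal(jsAlpha(A, B)@perRow, jsAlpha(B, A)@perRow, tolerance = 1e-12)
  expect_true(all(jsAlpha(A, B)@perRow >= 0 & jsAlpha(A, B)@perRow <= 1))
})

test_that("ML decoding: perfect for separated profiles, invariant to labels", {
  uD <- matrix(1e-4, 4, 4) + diag(4) * 50
  dimnames(uD) <- list(paste0("s", 1:4), NULL)
  prof <- mkProfiles(uD)
  test <- simulateBinnedResponse(prof, 40, seed = 4, sourceId = "t")
  repD <- fractionCorrect(prof, test)
  expect_equal(repD@overall, 1)

  # appending a cell with option-independent profiles changes nothing
  flat <- mkProfiles(matrix(2, 4, 4, dimnames = list(paste0("s", 1:4), NULL)))
  flatResp <- simulateBinnedResponse(flat, 40, seed = 5, sourceId = "t2")
  rep2 <- fractionCorrect(list(prof, flat), list(test, flatResp))
  expect_equal(rep2@perStimulus, repD@perStimulus)

  # relabeling the options permutes but does not change performance
  prm <- c(3, 1, 4, 2)
  uP <- uD[prm, ]; rownames(uP) <- paste0("s", 1:4)
  cntP <- counts(test)[, prm, , drop = FALSE]
  dimnames(cntP)[[2]] <- paste0("s", 1:4)
  testP <- new("BinnedResponse", counts = cntP, binWidth = 0.25,
               trialIds = test@trialIds, sourceId = "t")
  repP <- fractionCorrect(mkProfiles(uP), testP)
  expect_equal(repP@overall, repD@overall)
})

test_that("2AFC: chance without contrast, perfect at high signal, 75% rule", {
  pop <- makePopulation(4, fracOn = 0.5, seed = 81)
  expect_equal(sum(vapply(pop, function(cc) cc@polarity == "ON", logical(1))),
               2)
  curves <- contrastSensitivity(pop, temporalFreqs = 2,
                                contrasts = c(1, 0.5, 0.001), nTrials = 150,
                                seed = 82)
  pc <- curves[[1]]
  expect_equal(pc@fractionCorrect[pc@contrasts == 0.001], 0.5,
               tolerance = 0.12)                  # ~3 binomial s.e.
  expect_gt(pc@fractionCorrect[pc@contrasts == 1], 0.95)
  # threshold is the lowest grid contrast reaching the 75% criterion
  reached <- pc@contrasts[pc@fractionCorrect >= 0.75]
  expect_equal(pc@threshold, min(reached))
  expect_equal(pc@sensitivity, 1 / pc@threshold)

  # undefined threshold when no contrast reaches criterion
  weak <- contrastSensitivity(pop, temporalFreqs = 2, contrasts = 0.001,
                              nTrials = 100, seed = 83)
  expect_true(is.na(weak[[1]]@threshold))
  expect_true(is.na(weak[[1]]@sensitivity))
})
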