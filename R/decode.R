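asMatrixQ <- function(Q) if (is(Q, "PosteriorMatrix")) Q@Q else Q

# trial x bin count matrix of one presented stimulus
sliceCounts <- function(arr, i) {
  d <- dim(arr)
  matrix(arr[, i, ], d[1], d[3])
}

# log p(r|s_j) for every test trial (rows) and stimulus j (columns), up to
# the shared log n! term; u floored as in responseLogProb.
trialLogLik <- function(cnt, u, floor = 1e-9) {
  u <- pmax(u, floor)
  cnt %*% t(log(u)) - rep(1, nrow(cnt)) %o% rowSums(u)
}

#' Average posterior stimulus matrix from Bayesian decoding
#'
#' For every test trial of presented stimulus i, forms the posterior
#' p(s_j | r) over the stimulus set by Bayes' rule from the independent-
#' Poisson likelihoods of the training rate profiles and the prior (uniform
#' by default), then averages the posteriors over the trials of each
#' presented stimulus: row i of the result is the average posterior when
#' stimulus i was shown. Training profiles and test trials must be disjoint
#' (checked through their trial ids when both carry the same provenance
#' tag).
#'
#' @param profiles training-half \linkS4class{RateProfiles}.
#' @param test test-half \linkS4class{BinnedResponse} (same stimulus set and
#'   bin width).
#' @param prior stimulus prior (uniform when NULL).
#' @param source "real" or "model" tag for the resulting matrix.
#' @return a \linkS4class{PosteriorMatrix}
#' @export
posteriorMatrix <- function(profiles, test, prior = NULL, source = "model") {
  stopifnot(is(profiles, "RateProfiles"), is(test, "BinnedResponse"))
  if (!identical(stimLabels(profiles), stimLabels(test)))
    stop("profiles and test responses must share the stimulus set")
  if (abs(profiles@binWidth - test@binWidth) > 1e-9)
    stop("profiles and test responses must share the bin width")
  if (nzchar(profiles@sourceId) && identical(profiles@sourceId, test@sourceId) &&
      length(intersect(profiles@trialIds, test@trialIds)))
    stop("training and test trials overlap; split the data first")
  u <- profiles@u
  nS <- nrow(u)
  prior <- checkPrior(prior, nS)
  Q <- matrix(0, nS, nS, dimnames = list(rownames(u), rownames(u)))
  for (i in seq_len(nS)) {
    L <- sweep(trialLogLik(sliceCounts(test@counts, i), u), 2,
               log(prior), `+`)
    post <- exp(L - rowLogSumExp(L))
    Q[i, ] <- colMeans(post)
  }
  new("PosteriorMatrix", Q = Q, nTrials = dim(test@counts)[1],
      binWidth = test@binWidth, source = source)
}

#' Shuffle-normalized MSE index between posterior matrices
#'
#' Row-by-row mean squared error between the model and reference matrices,
#' each row normalized by the average MSE between the reference row and
#' random within-row permutations of the model row. 0 means the rows are
#' identical; 1 means they match no better than a randomly shuffled row;
#' values above 1 occur and are never clipped. The alpha value is the median
#' across rows. Rows whose shuffle denominator is zero (constant model row)
#' are excluded with a message.
#'
#' @param Qmodel,Qreal \linkS4class{PosteriorMatrix} objects or plain
#'   row-stochastic matrices of equal shape.
#' @param nShuffles within-row permutations for the normalizer.
#' @param seed RNG seed for the permutations.
#' @return an \linkS4class{AlphaScore} of kind "MSE"
#' @export
mseAlpha <- function(Qmodel, Qreal, nShuffles = 100, seed = NULL) {
  Qm <- asMatrixQ(Qmodel); Qr <- asMatrixQ(Qreal)
  stopifnot(identical(dim(Qm), dim(Qr)))
  nS <- ncol(Qm)
  perRow <- withSeed(seed, vapply(seq_len(nrow(Qm)), function(i) {
    num <- mean((Qm[i, ] - Qr[i, ])^2)
    shuf <- vapply(seq_len(nShuffles), function(s)
      mean((Qm[i, sample.int(nS)] - Qr[i, ])^2), numeric(1))
    den <- mean(shuf)
    if (den == 0) NA_real_ else num / den
  }, numeric(1)))
  if (anyNA(perRow))
    message(sum(is.na(perRow)),
            " row(s) with zero shuffle MSE excluded from the MSE alpha")
  pr <- perRow[!is.na(perRow)]
  new("AlphaScore", kind = "MSE", perRow = perRow,
      alpha = if (length(pr)) median(pr) else NA_real_, units = "")
}

# Jeffreys-style add-half regularization of a posterior row at a trial
# count: counts-equivalent q*n + 0.5 per bin, renormalized.
regularizeRow <- function(q, nTrials) {
  (q * nTrials + 0.5) / (nTrials + 0.5 * length(q))
}

klRow <- function(p, q) {
  # D(p || q) in bits with 0 log 0 = 0; infinite when q has a zero where p
  # does not (plug-in mode only).
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' Kullback-Leibler alpha between posterior matrices
#'
#' Per-row KL divergence D(real || model) in bits; the alpha value is the
#' median across rows. By default each row is first regularized by the
#' add-half rule at the row's trial count, \eqn{(q n + 1/2)/(n + N/2)};
#' with \code{regularize = FALSE} the plug-in divergence is computed without
#' regularization (the analytic reference mode: a delta row against a
#' uniform row over 30 stimuli gives log2(30) = 4.9 bits, the stimulus
#' entropy).
#'
#' @param Qmodel,Qreal \linkS4class{PosteriorMatrix} objects or matrices.
#' @param nTrials trial count behind each row, used by the regularizer;
#'   defaults to the matrices' own count (or 1, plain add-half, for bare
#'   matrices).
#' @param regularize apply the add-half regularization.
#' @param direction "real.model" for D(real || model) (default) or
#'   "model.real".
#' @return an \linkS4class{AlphaScore} of kind "KL" (bits)
#' @export
klAlpha <- function(Qmodel, Qreal, nTrials = NULL, regularize = TRUE,
                    direction = c("real.model", "model.real")) {
  direction <- match.arg(direction)
  if (is.null(nTrials))
    nTrials <- if (is(Qreal, "PosteriorMatrix") && Qreal@nTrials > 0)
      Qreal@nTrials else 1
  Qm <- asMatrixQ(Qmodel); Qr <- asMatrixQ(Qreal)
  stopifnot(identical(dim(Qm), dim(Qr)))
  perRow <- vapply(seq_len(nrow(Qm)), function(i) {
    m <- Qm[i, ]; r <- Qr[i, ]
    if (regularize) {
      m <- regularizeRow(m, nTrials)
      r <- regularizeRow(r, nTrials)
    }
    if (direction == "real.model") klRow(r, m) else klRow(m, r)
  }, numeric(1))
  new("AlphaScore", kind = "KL", perRow = perRow, alpha = median(perRow),
      units = "bits")
}

#' Jensen-Shannon alpha between posterior matrices
#'
#' Per-row Jensen-Shannon divergence in bits (base-2 logarithm, midpoint
#' mixture), computed from the plug-in rows without regularization -- the
#' JS divergence is finite for any pair of distributions, so none is needed.
#' It is symmetric and bounded in [0, 1]: rows concentrated on different
#' stimuli reach the maximum of 1 bit. The alpha value is the median across
#' rows.
#'
#' @param Qmodel,Qreal \linkS4class{PosteriorMatrix} objects or matrices.
#' @return an \linkS4class{AlphaScore} of kind "JS" (bits)
#' @export
jsAlpha <- function(Qmodel, Qreal) {
  Qm <- asMatrixQ(Qmodel); Qr <- asMatrixQ(Qreal)
  stopifnot(identical(dim(Qm), dim(Qr)))
  perRow <- vapply(seq_len(nrow(Qm)), function(i) {
    m <- Qm[i, ]; r <- Qr[i, ]
    mid <- (m + r) / 2
    0.5 * klRow(r, mid) + 0.5 * klRow(m, mid)
  }, numeric(1))
  new("AlphaScore", kind = "JS", perRow = perRow, alpha = median(perRow),
      units = "bits")
}

#' Maximum-likelihood decoding fraction correct
#'
#' Decodes each test trial as the stimulus with the highest posterior under
#' the training rate profiles, treating the cells of a population as
#' conditionally independent (their log-likelihoods add). A trial is correct
#' when the decoded stimulus is the presented one. Ties in the argmax are
#' broken deterministically toward the lowest option index and their rate is
#' reported.
#'
#' @param profiles a \linkS4class{RateProfiles} or list of them (one per
#'   cell, shared stimulus set).
#' @param test a \linkS4class{BinnedResponse} or list matching
#'   \code{profiles}; trial rows are aligned across cells (same trial).
#' @param prior stimulus prior over the options (uniform when NULL).
#' @param options subset of stimulus labels to decode among; defaults to
#'   all.
#' @return a \linkS4class{DecodeReport}
#' @export
fractionCorrect <- function(profiles, test, prior = NULL, options = NULL) {
  if (is(profiles, "RateProfiles")) profiles <- list(profiles)
  if (is(test, "BinnedResponse")) test <- list(test)
  stopifnot(length(profiles) == length(test), length(profiles) >= 1)
  labs <- stimLabels(profiles[[1]])
  if (is.null(options)) options <- labs
  stopifnot(all(options %in% labs))
  optIdx <- match(options, labs)
  nOpt <- length(options)
  prior <- checkPrior(prior, nOpt)
  nT <- dim(test[[1]]@counts)[1]
  nTies <- 0L
  perStim <- setNames(numeric(nOpt), options)
  for (oi in seq_len(nOpt)) {
    i <- optIdx[oi]
    L <- matrix(0, nT, nOpt)
    for (m in seq_along(profiles)) {
      cnt <- sliceCounts(test[[m]]@counts, i)
      L <- L + trialLogLik(cnt, profiles[[m]]@u[optIdx, , drop = FALSE])
    }
    L <- sweep(L, 2, log(prior), `+`)
    dec <- max.col(L, ties.method = "first")
    nTies <- nTies + sum(rowSums(L == apply(L, 1, max)) > 1L)
    perStim[oi] <- mean(dec == oi)
  }
  new("DecodeReport", perStimulus = perStim, overall = mean(perStim),
      nTrials = nT, nCells = length(profiles), options = options,
      tieRate = nTies / (nT * nOpt))
}

#' 2AFC contrast sensitivity of a model population
#'
#' Simulates the grating-present / grating-absent two-alternative forced
#' choice for a population of model cells: at each (temporal frequency,
#' contrast) the cells' expected responses to a 1 s drifting-grating segment
#' and to a uniform gray segment define the two response models; Poisson
#' responses are simulated for present and absent trials in equal numbers
#' (catch rate 1/2) and decoded by conditionally independent maximum
#' likelihood. The contrast threshold at each frequency is the lowest grid
#' contrast with at least 75% correct decisions, the criterion of
#' two-alternative forced-choice psychophysics; contrast sensitivity is its
#' reciprocal. By default only ON-tagged cells are used, mirroring the
#' optomotor pathway (only ON cells project to the accessory optic system).
#'
#' @param cells list of \linkS4class{LNPCell}.
#' @param temporalFreqs grating temporal frequencies (Hz).
#' @param contrasts contrast grid in (0, 1]; evaluated in descending order.
#' @param spatialFreq grating spatial frequency (cycles/degree).
#' @param nTrials present trials (and equally many absent trials) per
#'   contrast.
#' @param binWidth decoding bin width (s).
#' @param meanLuminance,width,height,degPerPixel,frameRate stimulus
#'   configuration.
#' @param onlyON restrict the population to ON-tagged cells.
#' @param criterion fraction correct defining the threshold (0.75).
#' @param seed master RNG seed.
#' @return list of \linkS4class{PsychometricCurve}, one per temporal
#'   frequency.
#' @seealso \code{\link{sensitivityTable}} for the peak-normalized tuning
#'   curve.
#' @export
contrastSensitivity <- function(cells, temporalFreqs, contrasts,
                                spatialFreq = 0.128, nTrials = 100,
                                binWidth = 1/8, meanLuminance = 1,
                                width = 32, height = 32, degPerPixel = 2.16,
                                frameRate = 15, onlyON = TRUE,
                                criterion = 0.75, seed = NULL) {
  if (onlyON) {
    keep <- vapply(cells, function(cc) cc@polarity == "ON", logical(1))
    if (any(keep)) cells <- cells[keep]
  }
  stopifnot(length(cells) >= 1, all(contrasts >= 0 & contrasts <= 1))
  contrasts <- sort(unique(contrasts), decreasing = TRUE)
  grayEns <- stimulusEnsemble(list(
    absent = makeGray(meanLuminance, duration = 1, width = width,
                      height = height, degPerPixel = degPerPixel,
                      frameRate = frameRate)))
  uAbsent <- lapply(cells, function(cc)
    modelRateProfiles(cc, grayEns, binWidth)@u["absent", ])
  lapply(temporalFreqs, function(tf) {
    fc <- vapply(seq_along(contrasts), function(ci) {
      cn <- contrasts[ci]
      seg <- if (cn > 0)
        makeDriftingGrating(tf, spatialFreq, cn, meanLuminance, duration = 1,
                            width = width, height = height,
                            degPerPixel = degPerPixel, frameRate = frameRate)
      else
        makeGray(meanLuminance, duration = 1, width = width, height = height,
                 degPerPixel = degPerPixel, frameRate = frameRate)
      ens <- stimulusEnsemble(list(present = seg))
      uPresent <- lapply(cells, function(cc)
        modelRateProfiles(cc, ens, binWidth)@u["present", ])
      sd0 <- if (is.null(seed)) NULL else
        moduleSeed(seed, sprintf("2afc_%g_%g", tf, cn))
      withSeed(sd0, {
        delta <- matrix(0, nTrials, 2)     # cols: present trials, absent trials
        for (m in seq_along(cells)) {
          up <- uPresent[[m]]; ua <- uAbsent[[m]]
          K <- length(up)
          rp <- matrix(rpois(nTrials * K, rep(up, each = nTrials)), nTrials, K)
          ra <- matrix(rpois(nTrials * K, rep(ua, each = nTrials)), nTrials, K)
          ll <- function(cnt, u) as.vector(trialLogLik(cnt, matrix(u, 1)))
          delta[, 1] <- delta[, 1] + ll(rp, up) - ll(rp, ua)
          delta[, 2] <- delta[, 2] + ll(ra, up) - ll(ra, ua)
        }
        # ties decode as the first option, "present"
        (sum(delta[, 1] >= 0) + sum(delta[, 2] < 0)) / (2 * nTrials)
      })
    }, numeric(1))
    reached <- contrasts[fc >= criterion & contrasts > 0]
    thr <- if (length(reached)) min(reached) else NA_real_
    new("PsychometricCurve", temporalFreq = tf, contrasts = contrasts,
        fractionCorrect = fc, threshold = thr,
        sensitivity = if (is.na(thr)) NA_real_ else 1 / thr)
  })
}

#' Tabulate contrast-sensitivity curves
#'
#' Collects the thresholds of a list of \linkS4class{PsychometricCurve}
#' objects and adds the sensitivity normalized to its own peak, the form in
#' which tuning curves are compared across conditions.
#'
#' @param curves list returned by \code{\link{contrastSensitivity}}.
#' @return data.frame with temporalFreq, threshold, sensitivity and
#'   normalizedSensitivity.
#' @export
sensitivityTable <- function(curves) {
  tf <- vapply(curves, function(p) p@temporalFreq, numeric(1))
  thr <- vapply(curves, function(p) p@threshold, numeric(1))
  sens <- vapply(curves, function(p) p@sensitivity, numeric(1))
  peak <- suppressWarnings(max(sens, na.rm = TRUE))
  data.frame(temporalFreq = tf, threshold = thr, sensitivity = sens,
             normalizedSensitivity = if (is.finite(peak)) sens / peak
                                     else rep(NA_real_, length(sens)))
}
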