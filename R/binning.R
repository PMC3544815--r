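#' Bin a spike raster into per-segment spike counts
#'
#' Cuts each trial's spike train into the labeled 1 s segments of a stream
#' and counts spikes in half-open bins [t, t + dt) of width \code{binWidth}
#' within each segment. Spikes in gray separators are excluded from the
#' segment responses; total within-segment spikes are conserved. If a label
#' occurs several times in the stream (repeats), the occurrences stack as
#' additional trials.
#'
#' @param raster a \linkS4class{SpikeRaster} recorded against the stream.
#' @param labels per-frame label track (from \code{\link{assembleStream}}),
#'   or a \linkS4class{StimulusStream}.
#' @param binWidth bin width in seconds; must divide the segment duration
#'   (1/4, 1/8, 1/16, 1/32 s for 1 s segments).
#' @param frameRate frame rate of the label track (taken from the stream if
#'   one is supplied).
#' @param sourceId provenance tag (defaults to the raster's cellId).
#' @return a \linkS4class{BinnedResponse}
#' @export
binCounts <- function(raster, labels, binWidth, frameRate = 15,
                      sourceId = NULL) {
  if (is(labels, "StimulusStream")) {
    frameRate <- frameRate(labels)
    labels <- labels@labels
  }
  runs <- rle(labels)
  segIdx <- which(runs$values != "GRAY")
  if (!length(segIdx)) stop("label track contains no stimulus segments")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths       # 0-based start frame
  segDur <- runs$lengths[segIdx][1] / frameRate
  K <- round(segDur / binWidth)
  if (abs(segDur / binWidth - K) > 1e-6 || K < 1)
    stop(sprintf("binWidth %.4g s does not divide the %.4g s segment", binWidth,
                 segDur))
  labs <- sort(unique(runs$values[segIdx]))
  occPer <- table(factor(runs$values[segIdx], levels = labs))
  if (length(unique(occPer)) > 1L)
    stop("labels must occur equally often in the stream")
  nOcc <- unname(occPer[1])
  nTr <- length(raster@trials)
  cnt <- array(0L, c(nTr * nOcc, length(labs), K),
               dimnames = list(NULL, labs, NULL))
  occSeen <- setNames(integer(length(labs)), labs)
  for (si in segIdx) {
    lab <- runs$values[si]
    occSeen[lab] <- occSeen[lab] + 1L
    t0 <- starts[si] / frameRate
    for (tr in seq_len(nTr)) {
      rel <- raster@trials[[tr]] - t0
      rel <- rel[rel >= 0 & rel < segDur]
      row <- (occSeen[lab] - 1L) * nTr + tr
      if (length(rel))
        cnt[row, lab, ] <- tabulate(pmin(floor(rel / binWidth), K - 1) + 1L,
                                    nbins = K)
    }
  }
  new("BinnedResponse", counts = cnt, binWidth = binWidth,
      trialIds = seq_len(nTr * nOcc),
      sourceId = if (is.null(sourceId)) raster@cellId else sourceId)
}

#' Trial-averaged rate profiles from binned responses
#'
#' The mean spike count per bin for each stimulus, the Poisson intensities
#' that parameterize p(response | stimulus).
#'
#' @param binned a \linkS4class{BinnedResponse} with >= 1 trial.
#' @return a \linkS4class{RateProfiles}
#' @export
rateProfiles <- function(binned) {
  stopifnot(is(binned, "BinnedResponse"), dim(binned@counts)[1] >= 1)
  u <- apply(binned@counts, c(2, 3), mean)
  new("RateProfiles", u = u, binWidth = binned@binWidth,
      nTrials = dim(binned@counts)[1], trialIds = binned@trialIds,
      sourceId = binned@sourceId)
}

# Integrate a piecewise-constant rate (per frame) over arbitrary bins:
# expected counts per bin of width binWidth over `duration` seconds.
resampleRateToCounts <- function(rate, frameRate, binWidth, duration) {
  K <- round(duration / binWidth)
  cum <- c(0, cumsum(rate) / frameRate)        # integral at frame edges
  edges <- seq(0, duration, by = binWidth)
  at <- stats::approx(x = (0:length(rate)) / frameRate, y = cum, xout = edges,
                      rule = 2)$y
  diff(at)
}

#' Model rate profiles for an ensemble
#'
#' Expected spike counts per bin of each segment under an LNP cell, computed
#' from the model's firing rate with a gray adaptation context: each segment
#' is preceded by 1.2 s of uniform gray at the mean luminance, so that the
#' profile does not depend on which segment happened to precede it in a
#' particular stream. The frame-resolution rate is integrated
#' piecewise-constant over the decoding bins.
#'
#' @param cell an \linkS4class{LNPCell}.
#' @param ensemble a \linkS4class{StimulusEnsemble} whose geometry covers the
#'   cell's patch.
#' @param binWidth decoding bin width in seconds (must divide the segment).
#' @return a \linkS4class{RateProfiles} with \code{nTrials = 0} (analytic).
#' @export
modelRateProfiles <- function(cell, ensemble, binWidth) {
  ref <- ensemble@segments[[1]]
  d <- dim(ref@frames)
  fps <- ref@frameRate
  nCtx <- ncol(cell@basis@basis)               # warm-up frames of gray
  segDur <- ensemble@segDuration
  K <- round(segDur / binWidth)
  if (abs(segDur / binWidth - K) > 1e-6)
    stop("binWidth does not divide the segment duration")
  labs <- names(ensemble@segments)
  u <- matrix(0, length(labs), K, dimnames = list(labs, NULL))
  ctx <- array(ref@meanLuminance, c(nCtx, d[2], d[3]))
  for (i in seq_along(labs)) {
    seg <- ensemble@segments[[i]]
    mov <- newStimulusMovie(
      frames = abind3(ctx, seg@frames), frameRate = fps,
      degPerPixel = seg@degPerPixel, meanLuminance = seg@meanLuminance,
      rmsContrast = seg@rmsContrast)
    lam <- firingRate(cell, mov)
    segRate <- lam[(nCtx + 1):(nCtx + dim(seg@frames)[1])]
    u[i, ] <- resampleRateToCounts(segRate, fps, binWidth, segDur)
  }
  new("RateProfiles", u = u, binWidth = binWidth, nTrials = 0,
      trialIds = integer(0), sourceId = cell@cellId)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  if (da[1]) out[seq_len(da[1]), , ] <- a
  if (db[1]) out[da[1] + seq_len(db[1]), , ] <- b
  out
}

#' Simulate binned Poisson responses from rate profiles
#'
#' Draws counts[trial, s, k] ~ Poisson(u[s, k]) -- the generative model that
#' Bayesian decoding and the Poisson information estimator assume.
#'
#' @param profiles a \linkS4class{RateProfiles}.
#' @param nTrials trials per stimulus.
#' @param seed RNG seed.
#' @param trialIds optional explicit trial ids (to keep simulated train and
#'   test sets disjoint); defaults to 1..nTrials.
#' @param sourceId provenance tag (defaults to the profiles' sourceId).
#' @return a \linkS4class{BinnedResponse}
#' @export
simulateBinnedResponse <- function(profiles, nTrials, seed = NULL,
                                   trialIds = NULL, sourceId = NULL) {
  u <- profiles@u
  nS <- nrow(u); K <- ncol(u)
  cnt <- withSeed(seed,
    array(rpois(nTrials * nS * K, rep(aperm(array(u, c(nS, K, nTrials)),
                                            c(3, 1, 2)))),
          c(nTrials, nS, K)))
  dimnames(cnt) <- list(NULL, rownames(u), NULL)
  if (is.null(trialIds)) trialIds <- seq_len(nTrials)
  new("BinnedResponse", counts = cnt, binWidth = profiles@binWidth,
      trialIds = as.integer(trialIds),
      sourceId = if (is.null(sourceId)) profiles@sourceId else sourceId)
}

#' Split binned trials into disjoint training and test halves
#'
#' Odd-indexed trials go to the training half, even-indexed to the test half
#' (deterministic), or a seeded random split. The halves keep their trial
#' ids, so downstream functions can verify train/test disjointness.
#'
#' @param binned a \linkS4class{BinnedResponse} with >= 2 trials.
#' @param fraction fraction assigned to the training half.
#' @param seed if non-NULL, split at random under this seed.
#' @return list with elements \code{train} and \code{test}.
#' @export
splitTrials <- function(binned, fraction = 0.5, seed = NULL) {
  nT <- dim(binned@counts)[1]
  stopifnot(nT >= 2, fraction > 0, fraction < 1)
  nTrain <- max(1L, round(nT * fraction))
  idx <- if (is.null(seed)) seq(1L, nT, by = 2L)[seq_len(min(nTrain, ceiling(nT / 2)))]
         else withSeed(seed, sort(sample.int(nT, nTrain)))
  take <- function(i) new("BinnedResponse",
    counts = binned@counts[i, , , drop = FALSE], binWidth = binned@binWidth,
    trialIds = binned@trialIds[i], sourceId = binned@sourceId)
  list(train = take(idx), test = take(setdiff(seq_len(nT), idx)))
}
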