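# Embed a cell's full filter into field-pixel coordinates so filters of
# cells with (possibly differently) estimated RF centers can be compared.
embedFilter <- function(cell, fieldDim) {
  nb <- ncol(cell@basis@basis)
  out <- matrix(0, nb, prod(fieldDim))
  px <- patchIndices(cell, c(NA, fieldDim))
  idx <- as.vector(outer(px$rows, (px$cols - 1L) * fieldDim[1], `+`))
  out[, idx] <- fullFilter(cell)
  out
}

# Training/test stimulus: white noise and a natural-like movie concatenated
# 50/50 by duration (the mixed-statistics protocol models are built on).
trainingMovie <- function(minutes, fieldDim, contrast = 0.16, seed = 1) {
  half <- minutes * 60 / 2
  wn <- makeBinaryWhiteNoise(1, contrast, half, width = fieldDim[2],
                             height = fieldDim[1],
                             seed = moduleSeed(seed, "whitenoise"))
  nat <- makeNaturalMovie(duration = half, width = fieldDim[2],
                          height = fieldDim[1], rmsContrast = contrast,
                          seed = moduleSeed(seed, "naturaltrain"))
  newStimulusMovie(abind3(wn@frames, nat@frames), wn@frameRate,
                   wn@degPerPixel, wn@meanLuminance, contrast)
}

#' End-to-end parameter-recovery run on a synthetic population
#'
#' Simulates a ground-truth LNP population, records its spike trains to a
#' mixed white-noise / natural-movie training stimulus, refits each cell
#' from its spikes alone by \code{\link{fitLNP}}, and evaluates the refits:
#' (1) Pearson correlation between true and fitted spatiotemporal filters,
#' (2) correlation between true and fitted firing rates on a held-out
#' stimulus, and optionally (3) mutual information carried about a
#' natural-snippet ensemble by the true versus the fitted model and (4) the
#' posterior-matrix alpha distances (MSE, KL, JS) between decoding with the
#' fitted model and decoding with the truth. The whole pipeline is
#' reproducible under the master \code{seed} (stage seeds are derived by
#' \code{\link{moduleSeed}}).
#'
#' @param nCells population size.
#' @param fracOn fraction of ON cells.
#' @param trainMinutes minutes of simulated training stimulus.
#' @param testMinutes minutes of held-out stimulus for the rate check.
#' @param nStim natural snippets in the evaluation ensemble.
#' @param nTrialsDecode trials per stimulus for each posterior-matrix half.
#' @param binWidth response bin width (s) for the information and posterior
#'   analyses.
#' @param mcSamples Monte-Carlo samples per information estimate.
#' @param nShuffles shuffles for the MSE alpha normalizer.
#' @param fieldDim stimulus field (rows, columns).
#' @param condition population preset ("photopic" or "scotopic").
#' @param config a \code{\link{fitConfig}}.
#' @param evaluate run the information / posterior evaluation stages.
#' @param seed master seed.
#' @return a list of class \code{RecoveryReport}: per-cell filter and
#'   held-out rate correlations, fit results, and (when evaluated)
#'   per-cell true/fitted information and alpha values.
#' @export
runRecovery <- function(nCells = 5, fracOn = 0.5, trainMinutes = 20,
                        testMinutes = 2, nStim = 30, nTrialsDecode = 25,
                        binWidth = 1/16, mcSamples = 20000, nShuffles = 100,
                        fieldDim = c(16L, 16L),
                        condition = "photopic", config = fitConfig(),
                        evaluate = TRUE, seed = 1) {
  cells <- makePopulation(nCells, fracOn, condition, fieldDim = fieldDim,
                          seed = moduleSeed(seed, "population"))
  train <- trainingMovie(trainMinutes, fieldDim,
                         seed = moduleSeed(seed, "train"))
  test <- trainingMovie(testMinutes, fieldDim,
                        seed = moduleSeed(seed, "heldout"))
  fits <- vector("list", nCells)
  filterCorr <- heldOutCorr <- numeric(nCells)
  for (i in seq_len(nCells)) {
    lam <- firingRate(cells[[i]], train)
    raster <- sampleSpikes(lam, 1, 1 / train@frameRate,
                           seed = moduleSeed(seed, paste0("spikes", i)),
                           cellId = cells[[i]]@cellId)
    fits[[i]] <- fitLNP(train, raster, basis = cells[[i]]@basis,
                        config = config)
    fc <- fittedCell(fits[[i]])
    filterCorr[i] <- abs(cor(as.vector(embedFilter(cells[[i]], fieldDim)),
                             as.vector(embedFilter(fc, fieldDim))))
    lamT <- firingRate(cells[[i]], test)
    lamF <- firingRate(fc, test)
    ok <- !is.na(lamT) & !is.na(lamF)
    heldOutCorr[i] <- cor(lamT[ok], lamF[ok])
  }
  rep <- list(cells = cells, fits = fits, filterCorr = filterCorr,
              heldOutCorr = heldOutCorr,
              medianFilterCorr = median(filterCorr),
              medianHeldOutCorr = median(heldOutCorr), seed = seed)
  if (evaluate) {
    ens <- makeNaturalEnsemble(nStim, duration = 1, width = fieldDim[2],
                               height = fieldDim[1],
                               seed = moduleSeed(seed, "ensemble"))
    miTrue <- miFit <- numeric(nCells)
    aMSE <- aKL <- aJS <- numeric(nCells)
    for (i in seq_len(nCells)) {
      uT <- modelRateProfiles(cells[[i]], ens, binWidth)
      uF <- modelRateProfiles(fittedCell(fits[[i]]), ens, binWidth)
      miTrue[i] <- miValue(mutualInformationPoisson(
        uT, mcSamples = mcSamples, method = "mc",
        seed = moduleSeed(seed, paste0("miT", i))))
      miFit[i] <- miValue(mutualInformationPoisson(
        uF, mcSamples = mcSamples, method = "mc",
        seed = moduleSeed(seed, paste0("miF", i))))
      simHalf <- function(u, tag, off)
        simulateBinnedResponse(u, nTrialsDecode,
                               seed = moduleSeed(seed, paste0(tag, i)),
                               trialIds = off + seq_len(nTrialsDecode),
                               sourceId = paste0(tag, i))
      qReal <- posteriorMatrix(rateProfiles(simHalf(uT, "realtrain", 0)),
                               simHalf(uT, "realtest", nTrialsDecode),
                               source = "real")
      qModel <- posteriorMatrix(rateProfiles(simHalf(uF, "modtrain", 0)),
                                simHalf(uF, "modtest", nTrialsDecode),
                                source = "model")
      aMSE[i] <- alphaValue(mseAlpha(qModel, qReal, nShuffles,
                                     seed = moduleSeed(seed, paste0("sh", i))))
      aKL[i] <- alphaValue(klAlpha(qModel, qReal))
      aJS[i] <- alphaValue(jsAlpha(qModel, qReal))
    }
    rep <- c(rep, list(miTrue = miTrue, miFit = miFit,
                       miRatio = miFit / miTrue, alphaMSE = aMSE,
                       alphaKL = aKL, alphaJS = aJS))
  }
  structure(rep, class = "RecoveryReport")
}

#' @export
print.RecoveryReport <- function(x, ...) {
  cat(sprintf("RecoveryReport: %d cells (seed %d)\n", length(x$cells), x$seed))
  cat(sprintf("  median filter correlation:   %.3f\n", x$medianFilterCorr))
  cat(sprintf("  median held-out rate corr.:  %.3f\n", x$medianHeldOutCorr))
  if (!is.null(x$miRatio)) {
    cat(sprintf("  MI fitted/true (median):     %.3f\n", median(x$miRatio)))
    cat(sprintf("  alpha medians: MSE %.3f, KL %.3f bits, JS %.3f bits\n",
                median(x$alphaMSE), median(x$alphaKL), median(x$alphaJS)))
  }
  invisible(x)
}
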