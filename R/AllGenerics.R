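#' @importFrom stats median sd coef lm optim rnorm rpois runif dpois qpois
#'   splinefun poisson glm.fit mvfft fft quantile cor setNames approx
#' @importFrom utils head read.csv write.csv
NULL

#' Frames of a stimulus movie
#' @param x a \linkS4class{StimulusMovie}
#' @return the (time x height x width) luminance array
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setMethod("frames", "StimulusMovie", function(x) x@frames)

#' Frame rate in Hz
#' @param x a \linkS4class{StimulusMovie} or \linkS4class{StimulusStream}
#' @return frames per second
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname frameRate
#' @export
setMethod("frameRate", "StimulusMovie", function(x) x@frameRate)

#' @rdname frameRate
#' @export
setMethod("frameRate", "StimulusStream", function(x) x@movie@frameRate)

#' Number of frames
#' @param x a \linkS4class{StimulusMovie}
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "StimulusMovie", function(x) dim(x@frames)[1])

#' Duration in seconds
#' @param x a \linkS4class{StimulusMovie} or \linkS4class{SpikeRaster}
#' @return duration in seconds
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname duration
#' @export
setMethod("duration", "StimulusMovie", function(x) dim(x@frames)[1] / x@frameRate)

#' @rdname duration
#' @export
setMethod("duration", "SpikeRaster", function(x) x@duration)

#' Number of distinct stimuli
#' @param x an ensemble, binned response, rate profiles or posterior matrix
#' @return integer count of distinct stimulus labels
#' @export
setGeneric("nStim", function(x) standardGeneric("nStim"))

#' @rdname nStim
#' @export
setMethod("nStim", "StimulusEnsemble", function(x) length(x@segments))

#' @rdname nStim
#' @export
setMethod("nStim", "BinnedResponse", function(x) dim(x@counts)[2])

#' @rdname nStim
#' @export
setMethod("nStim", "RateProfiles", function(x) nrow(x@u))

#' @rdname nStim
#' @export
setMethod("nStim", "PosteriorMatrix", function(x) nrow(x@Q))

#' Stimulus labels
#' @param x an ensemble, stream, binned response or rate profiles
#' @return character vector of labels
#' @export
setGeneric("stimLabels", function(x) standardGeneric("stimLabels"))

#' @rdname stimLabels
#' @export
setMethod("stimLabels", "StimulusEnsemble", function(x) names(x@segments))

#' @rdname stimLabels
#' @export
setMethod("stimLabels", "StimulusStream", function(x) x@labels)

#' @rdname stimLabels
#' @export
setMethod("stimLabels", "BinnedResponse", function(x) dimnames(x@counts)[[2]])

#' @rdname stimLabels
#' @export
setMethod("stimLabels", "RateProfiles", function(x) rownames(x@u))

#' Spike counts array
#' @param x a \linkS4class{BinnedResponse}
#' @return trial x stimulus x bin integer array
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname counts
#' @export
setMethod("counts", "BinnedResponse", function(x) x@counts)

#' Mean-count matrix of rate profiles
#' @param x a \linkS4class{RateProfiles}
#' @return stimulus x bin matrix of mean counts per bin
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname profileMatrix
#' @export
setMethod("profileMatrix", "RateProfiles", function(x) x@u)

#' Posterior matrix
#' @param x a \linkS4class{PosteriorMatrix}
#' @return presented x decoded probability matrix (rows sum to 1)
#' @export
setGeneric("posterior", function(x) standardGeneric("posterior"))

#' @rdname posterior
#' @export
setMethod("posterior", "PosteriorMatrix", function(x) x@Q)

#' Median row distance (alpha value)
#' @param x an \linkS4class{AlphaScore}
#' @return the alpha value (median of the per-row distances)
#' @export
setGeneric("alphaValue", function(x) standardGeneric("alphaValue"))

#' @rdname alphaValue
#' @export
setMethod("alphaValue", "AlphaScore", function(x) x@alpha)

#' Mutual information value in bits
#' @param x an \linkS4class{MIResult}
#' @return information in bits
#' @export
setGeneric("miValue", function(x) standardGeneric("miValue"))

#' @rdname miValue
#' @export
setMethod("miValue", "MIResult", function(x) x@value)

#' Fitted cell of a fit result
#' @param x a \linkS4class{FitResult}
#' @return the fitted \linkS4class{LNPCell}
#' @export
setGeneric("fittedCell", function(x) standardGeneric("fittedCell"))

#' @rdname fittedCell
#' @export
setMethod("fittedCell", "FitResult", function(x) x@cell)

#' Temporal filter of an LNP cell
#'
#' Expands the basis coefficients into the full temporal filter (one weight
#' per time bin, most recent bin first).
#' @param x an \linkS4class{LNPCell}
#' @return numeric vector of length nBins
#' @export
setGeneric("temporalFilter", function(x) standardGeneric("temporalFilter"))

#' @rdname temporalFilter
#' @export
setMethod("temporalFilter", "LNPCell",
  function(x) as.vector(x@temporalCoeffs %*% x@basis@basis))

#' Full spatiotemporal filter of an LNP cell
#'
#' The outer product of the temporal filter (rows, most recent lag first) and
#' the vectorized 10x10 spatial weights (columns).
#' @param x an \linkS4class{LNPCell}
#' @return nBins x 100 numeric matrix
#' @export
setGeneric("fullFilter", function(x) standardGeneric("fullFilter"))

#' @rdname fullFilter
#' @export
setMethod("fullFilter", "LNPCell",
  function(x) outer(temporalFilter(x), as.vector(x@spatialWeights)))

setMethod("show", "StimulusMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("StimulusMovie: %d frames (%.3g s at %g Hz), %dx%d px (%.3g deg/px)\n",
              d[1], d[1] / object@frameRate, object@frameRate, d[2], d[3],
              object@degPerPixel))
  cat(sprintf("  mean luminance %.4g, nominal RMS contrast %.4g\n",
              object@meanLuminance, object@rmsContrast))
})

setMethod("show", "StimulusEnsemble", function(object) {
  cat(sprintf("StimulusEnsemble: %d segments of %.3g s (+%.3g s gray), uniform prior: %s\n",
              length(object@segments), object@segDuration, object@grayDuration,
              if (length(unique(object@prior)) == 1L) "yes" else "no"))
})

setMethod("show", "StimulusStream", function(object) {
  cat(sprintf("StimulusStream: %d frames, %d segment labels + GRAY\n",
              length(object@labels), length(setdiff(unique(object@labels), "GRAY"))))
})

setMethod("show", "TemporalBasis", function(object) {
  cat(sprintf("TemporalBasis: %d raised cosines on %d bins of %.3g s (span %.3g s)\n",
              nrow(object@basis), ncol(object@basis), object@binWidth,
              ncol(object@basis) * object@binWidth))
})

setMethod("show", "Nonlinearity", function(object) {
  if (object@kind == "exponential")
    cat(sprintf("Nonlinearity: exponential, gain %.3g, offset %.3g, floor %.3g sp/s\n",
                object@gain, object@offset, object@rateFloor))
  else
    cat(sprintf("Nonlinearity: cubic spline, %d knots on [%.3g, %.3g], floor %.3g sp/s\n",
                length(object@knots), min(object@knots), max(object@knots),
                object@rateFloor))
})

setMethod("show", "LNPCell", function(object) {
  cat(sprintf("LNPCell '%s' (%s): RF at (%d, %d), %d temporal coefficients, %s nonlinearity\n",
              object@cellId, object@polarity, object@rfCenter[1],
              object@rfCenter[2], length(object@temporalCoeffs),
              object@nonlinearity@kind))
})

setMethod("show", "SpikeRaster", function(object) {
  n <- vapply(object@trials, length, integer(1))
  cat(sprintf("SpikeRaster '%s': %d trials of %.3g s, %.3g spikes/trial (mean rate %.3g sp/s)\n",
              object@cellId, length(n), object@duration, mean(n),
              mean(n) / object@duration))
})

setMethod("show", "BinnedResponse", function(object) {
  d <- dim(object@counts)
  cat(sprintf("BinnedResponse: %d trials x %d stimuli x %d bins of %.4g s\n",
              d[1], d[2], d[3], object@binWidth))
})

setMethod("show", "RateProfiles", function(object) {
  cat(sprintf("RateProfiles: %d stimuli x %d bins of %.4g s (%s)\n",
              nrow(object@u), ncol(object@u), object@binWidth,
              if (object@nTrials > 0)
                sprintf("averaged over %g trials", object@nTrials)
              else "analytic"))
})

setMethod("show", "MIResult", function(object) {
  cat(sprintf("MIResult: %.4g bits (%s%s, dt = %.4g s%s)\n", object@value,
              object@estimator, if (object@debiased) ", debiased" else "",
              object@binWidth,
              if (is.finite(object@se)) sprintf(", se %.3g", object@se) else ""))
})

setMethod("show", "PosteriorMatrix", function(object) {
  cat(sprintf("PosteriorMatrix (%s): %d x %d, %g trials/row, dt = %.4g s\n",
              object@source, nrow(object@Q), ncol(object@Q), object@nTrials,
              object@binWidth))
})

setMethod("show", "AlphaScore", function(object) {
  cat(sprintf("AlphaScore (%s): alpha = %.4g%s over %d rows (%d excluded)\n",
              object@kind, object@alpha,
              if (nzchar(object@units)) paste0(" ", object@units) else "",
              length(object@perRow), sum(is.na(object@perRow))))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: Z %.6g -> %.6g nats over %d stages, %sconverged\n",
              object@zTrajectory[1], object@zTrajectory[length(object@zTrajectory)],
              length(object@zTrajectory), if (object@converged) "" else "NOT "))
})

setMethod("show", "DecodeReport", function(object) {
  cat(sprintf("DecodeReport: overall fraction correct %.4g (%d cells, %d options, chance %.3g, tie rate %.3g)\n",
              object@overall, object@nCells, length(object@options),
              1 / length(object@options), object@tieRate))
})

setMethod("show", "PsychometricCurve", function(object) {
  cat(sprintf("PsychometricCurve at %.3g Hz: threshold %s, sensitivity %s\n",
              object@temporalFreq,
              if (is.na(object@threshold)) "undefined" else
                sprintf("%.4g", object@threshold),
              if (is.na(object@sensitivity)) "undefined" else
                sprintf("%.4g", object@sensitivity)))
})
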