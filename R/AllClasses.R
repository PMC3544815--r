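#' @import methods
NULL

#' StimulusMovie: a stack of luminance frames
#'
#' Container for a spatiotemporal stimulus: a 3-D array of linear luminance
#' values (time x height x width, arbitrary linear units), the frame rate, the
#' visual-angle scale of a pixel, and the nominal mean luminance and RMS
#' contrast of the generator that produced it.
#'
#' @slot frames numeric 3-D array, dimensions (frames, rows, columns); finite,
#'   non-negative luminance.
#' @slot frameRate frames per second (Hz), > 0.
#' @slot degPerPixel degrees of visual angle subtended by one pixel, > 0.
#' @slot meanLuminance nominal mean luminance, same units as \code{frames}.
#' @slot rmsContrast nominal RMS contrast (a luminance s.d.), same units.
#' @exportClass StimulusMovie
setClass("StimulusMovie",
  representation(frames = "array", frameRate = "numeric",
                 degPerPixel = "numeric", meanLuminance = "numeric",
                 rmsContrast = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@frames)) != 3L)
      msg <- c(msg, "frames must be a 3-D array (time x height x width)")
    if (length(object@frames) && !all(is.finite(object@frames)))
      msg <- c(msg, "frames must be finite")
    if (length(object@frames) && any(object@frames < 0))
      msg <- c(msg, "frames must be non-negative luminance values")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (length(object@degPerPixel) != 1L || object@degPerPixel <= 0)
      msg <- c(msg, "degPerPixel must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' StimulusEnsemble: a labeled set of equal-length stimulus segments
#'
#' An ordered, named list of \linkS4class{StimulusMovie} segments of common
#' duration and geometry, together with the gray-separator duration used when
#' the segments are assembled into a presentation stream and the (uniform by
#' default) prior over segment labels. The distinct labels define the discrete
#' stimulus set for information and decoding analyses.
#'
#' @slot segments named list of \linkS4class{StimulusMovie}, one per label.
#' @slot prior named numeric vector of label probabilities, summing to 1.
#' @slot segDuration segment duration in seconds (default 1).
#' @slot grayDuration gray-separator duration in seconds (default 1/3).
#' @exportClass StimulusEnsemble
setClass("StimulusEnsemble",
  representation(segments = "list", prior = "numeric",
                 segDuration = "numeric", grayDuration = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!length(object@segments)) msg <- c(msg, "ensemble needs >= 1 segment")
    if (is.null(names(object@segments)) || anyDuplicated(names(object@segments)))
      msg <- c(msg, "segments must have unique names (labels)")
    if (!all(vapply(object@segments, is, TRUE, class2 = "StimulusMovie")))
      msg <- c(msg, "all segments must be StimulusMovie objects")
    else {
      dims <- vapply(object@segments, function(m) dim(m@frames), numeric(3))
      if (length(object@segments) > 1L && any(apply(dims, 1, function(x) length(unique(x)) > 1L)))
        msg <- c(msg, "all segments must share frame count and geometry")
      fr <- vapply(object@segments, function(m) m@frameRate, numeric(1))
      if (length(unique(fr)) > 1L) msg <- c(msg, "all segments must share frameRate")
    }
    if (abs(sum(object@prior) - 1) > 1e-8) msg <- c(msg, "prior must sum to 1")
    if (length(object@prior) != length(object@segments))
      msg <- c(msg, "prior must have one entry per segment")
    if (length(msg)) msg else TRUE
  })

#' StimulusStream: an assembled movie plus its per-frame label track
#'
#' The concatenation segment, gray, segment, gray, ... of an ensemble's
#' segments in a stated order, with every frame labeled by its segment label
#' or \code{"GRAY"}. The label track is a partition: each frame carries
#' exactly one label.
#'
#' @slot movie the concatenated \linkS4class{StimulusMovie}.
#' @slot labels character vector, one label per frame.
#' @exportClass StimulusStream
setClass("StimulusStream",
  representation(movie = "StimulusMovie", labels = "character"),
  validity = function(object) {
    if (dim(object@movie@frames)[1] != length(object@labels))
      "labels must have one entry per frame" else TRUE
  })

#' TemporalBasis: raised-cosine temporal basis
#'
#' A bank of raised-cosine bumps on a log-stretched time axis, evaluated on a
#' grid of time bins; used to parameterize temporal filters compactly. Each
#' basis function is non-negative, unimodal, and attains 1 at its peak.
#'
#' @slot basis numeric matrix, nBasis x nBins; row j is basis function j.
#' @slot binWidth time-bin width in seconds (67 ms by default).
#' @slot stretch log-stretch constant (seconds) of the time axis.
#' @exportClass TemporalBasis
setClass("TemporalBasis",
  representation(basis = "matrix", binWidth = "numeric", stretch = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@basis < -1e-12) || any(object@basis > 1 + 1e-12))
      msg <- c(msg, "basis values must lie in [0, 1]")
    if (nrow(object@basis) > ncol(object@basis))
      msg <- c(msg, "nBasis must not exceed nBins")
    if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
    if (length(msg)) msg else TRUE
  })

#' Nonlinearity: the static nonlinearity of an LNP cascade
#'
#' Maps the generator signal (linear-filter output) to a firing rate in
#' spikes/s. Either exponential, \eqn{N(g) = exp(gain \cdot g + offset)}, or an
#' interpolating cubic spline through (knot, value) pairs with linear
#' extrapolation beyond the outer knots. Output is clamped below at
#' \code{rateFloor} so log-likelihoods stay finite.
#'
#' @slot kind "exponential" or "cubic_spline".
#' @slot gain,offset exponential parameters (unused for splines).
#' @slot knots,values spline knot locations (generator-signal units) and the
#'   rates (spikes/s) the spline passes through at the knots.
#' @slot rateFloor minimum rate in spikes/s (small positive).
#' @exportClass Nonlinearity
setClass("Nonlinearity",
  representation(kind = "character", gain = "numeric", offset = "numeric",
                 knots = "numeric", values = "numeric", rateFloor = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!object@kind %in% c("exponential", "cubic_spline"))
      msg <- c(msg, "kind must be 'exponential' or 'cubic_spline'")
    if (object@rateFloor <= 0) msg <- c(msg, "rateFloor must be positive")
    if (object@kind == "cubic_spline") {
      if (length(object@knots) < 4L)
        msg <- c(msg, "cubic spline needs >= 4 knots")
      if (length(object@knots) != length(object@values))
        msg <- c(msg, "knots and values must have equal length")
      if (is.unsorted(object@knots, strictly = TRUE))
        msg <- c(msg, "knots must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
  })

#' LNPCell: a linear-nonlinear-Poisson model cell
#'
#' A separable spatiotemporal linear filter (10x10 spatial weight patch,
#' centered on the receptive field, times a temporal filter expressed in a
#' raised-cosine basis) followed by a static nonlinearity. The full linear
#' filter is the outer product of the temporal and spatial parts. The filter
#' output (generator signal) drives an inhomogeneous Poisson spike generator.
#'
#' @slot rfCenter integer (row, column) of the receptive-field center; the
#'   spatial patch spans rows \code{rfCenter[1] - 4 .. rfCenter[1] + 5} and
#'   likewise for columns.
#' @slot spatialWeights 10 x 10 numeric matrix, \code{[row, column]}.
#' @slot temporalCoeffs coefficients on the rows of \code{basis}.
#' @slot basis the \linkS4class{TemporalBasis} the coefficients refer to.
#' @slot nonlinearity a \linkS4class{Nonlinearity}.
#' @slot polarity "ON", "OFF" or "untyped" (metadata only; no algorithm uses it
#'   except the optomotor-style ON-population filter in
#'   \code{\link{contrastSensitivity}}).
#' @slot cellId identifier string.
#' @exportClass LNPCell
setClass("LNPCell",
  representation(rfCenter = "integer", spatialWeights = "matrix",
                 temporalCoeffs = "numeric", basis = "TemporalBasis",
                 nonlinearity = "Nonlinearity", polarity = "character",
                 cellId = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!identical(dim(object@spatialWeights), c(10L, 10L)))
      msg <- c(msg, "spatialWeights must be a 10x10 matrix")
    if (length(object@temporalCoeffs) != nrow(object@basis@basis))
      msg <- c(msg, "temporalCoeffs length must match the basis")
    if (length(object@rfCenter) != 2L)
      msg <- c(msg, "rfCenter must be (row, column)")
    if (sum(object@spatialWeights^2) * sum(object@temporalCoeffs^2) <= 0)
      msg <- c(msg, "filter energy must be positive")
    if (!object@polarity %in% c("ON", "OFF", "untyped"))
      msg <- c(msg, "polarity must be ON, OFF or untyped")
    if (length(msg)) msg else TRUE
  })

#' SpikeRaster: per-trial spike times
#'
#' @slot trials list of numeric vectors of spike times (seconds), each sorted
#'   and contained in [0, duration).
#' @slot duration trial duration in seconds.
#' @slot cellId identifier of the cell that produced the raster.
#' @exportClass SpikeRaster
setClass("SpikeRaster",
  representation(trials = "list", duration = "numeric", cellId = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!length(object@trials)) msg <- c(msg, "raster needs >= 1 trial")
    ok <- vapply(object@trials, function(tt)
      !is.unsorted(tt) && (!length(tt) || (min(tt) >= 0 && max(tt) < object@duration)),
      logical(1))
    if (!all(ok))
      msg <- c(msg, "spike times must be sorted and within [0, duration)")
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    if (length(msg)) msg else TRUE
  })

#' BinnedResponse: spike counts per trial, stimulus and time bin
#'
#' Spike counts of one cell in half-open time bins of width \code{binWidth}
#' within each 1 s stimulus segment, organized as a 3-D array
#' (trial x stimulus x bin). Gray-separator spikes are excluded.
#'
#' @slot counts non-negative integer array, trial x stimulus x bin, with
#'   stimulus labels as dimnames of the second dimension.
#' @slot binWidth bin width in seconds (1/4, 1/8, 1/16 or 1/32 for the
#'   standard segment analyses).
#' @slot trialIds integer ids of the trials (rows), used to keep train/test
#'   splits disjoint.
#' @slot sourceId provenance tag; two responses with the same non-empty
#'   sourceId are assumed to come from the same recording.
#' @exportClass BinnedResponse
setClass("BinnedResponse",
  representation(counts = "array", binWidth = "numeric",
                 trialIds = "integer", sourceId = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@counts)) != 3L)
      msg <- c(msg, "counts must be trial x stimulus x bin")
    if (length(object@counts) && (any(object@counts < 0) ||
        any(object@counts != round(object@counts))))
      msg <- c(msg, "counts must be non-negative integers")
    if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
    if (length(object@trialIds) != dim(object@counts)[1])
      msg <- c(msg, "trialIds must match the number of trial rows")
    if (length(msg)) msg else TRUE
  })

#' RateProfiles: trial-averaged mean count per bin per stimulus
#'
#' The per-stimulus mean spike count in each time bin -- the Poisson
#' intensities that parameterize the conditional response distribution
#' p(response | stimulus) used for information estimates and Bayesian
#' decoding.
#'
#' @slot u numeric matrix, stimulus x bin, of mean counts per bin (>= 0).
#' @slot binWidth bin width in seconds.
#' @slot nTrials number of trials averaged (0 when profiles are computed
#'   analytically from a model).
#' @slot trialIds ids of the trials averaged (empty for analytic profiles).
#' @slot sourceId provenance tag (see \linkS4class{BinnedResponse}).
#' @exportClass RateProfiles
setClass("RateProfiles",
  representation(u = "matrix", binWidth = "numeric", nTrials = "numeric",
                 trialIds = "integer", sourceId = "character"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@u < 0)) msg <- c(msg, "mean counts must be non-negative")
    if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
    if (length(msg)) msg else TRUE
  })

#' MIResult: a mutual-information estimate
#'
#' @slot value mutual information in bits.
#' @slot estimator "poisson_mc", "poisson_exact" or "quartile".
#' @slot binWidth response bin width in seconds.
#' @slot mcSamples Monte-Carlo samples used (0 for exact enumeration).
#' @slot se Monte-Carlo standard error of the estimate (NA when exact).
#' @slot seed seed used for sampling (NA when none).
#' @slot debiased whether quadratic-extrapolation debiasing was applied.
#' @exportClass MIResult
setClass("MIResult",
  representation(value = "numeric", estimator = "character",
                 binWidth = "numeric", mcSamples = "numeric", se = "numeric",
                 seed = "numeric", debiased = "logical"))

#' PosteriorMatrix: average posterior stimulus distributions
#'
#' Row i is the average, over the test trials on which stimulus i was
#' presented, of the Bayesian posterior over stimuli given the single-trial
#' response. Rows are probability distributions (sum to 1).
#'
#' @slot Q numeric matrix, presented stimulus x decoded stimulus.
#' @slot nTrials test trials averaged per row.
#' @slot binWidth response bin width in seconds.
#' @slot source "real" or "model" (metadata).
#' @exportClass PosteriorMatrix
setClass("PosteriorMatrix",
  representation(Q = "matrix", nTrials = "numeric", binWidth = "numeric",
                 source = "character"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@Q < 0)) msg <- c(msg, "posterior entries must be >= 0")
    if (any(abs(rowSums(object@Q) - 1) > 1e-9))
      msg <- c(msg, "each posterior row must sum to 1 (within 1e-9)")
    if (length(msg)) msg else TRUE
  })

#' AlphaScore: a row-wise posterior-matrix distance and its median
#'
#' Row-by-row distances between a model average-posterior matrix and a
#' reference one, and their median, the alpha value. Kinds: "MSE"
#' (shuffle-normalized mean squared error; 0 = identical, ~1 = shuffle-level
#' mismatch, values > 1 possible and never clipped), "KL" (Kullback-Leibler
#' divergence in bits), "JS" (Jensen-Shannon divergence in bits, in [0, 1]).
#'
#' @slot kind "MSE", "KL" or "JS".
#' @slot perRow distances per presented stimulus (may contain NA where a row
#'   is degenerate and was excluded).
#' @slot alpha median of \code{perRow} (NA-removed).
#' @slot units "" for MSE, "bits" for KL and JS.
#' @exportClass AlphaScore
setClass("AlphaScore",
  representation(kind = "character", perRow = "numeric", alpha = "numeric",
                 units = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@kind %in% c("MSE", "KL", "JS"))
      msg <- c(msg, "kind must be MSE, KL or JS")
    pr <- object@perRow[!is.na(object@perRow)]
    if (object@kind %in% c("KL", "JS") && any(pr < -1e-12))
      msg <- c(msg, "divergences must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' FitResult: outcome of a maximum-likelihood LNP fit
#'
#' @slot cell the fitted \linkS4class{LNPCell}.
#' @slot zTrajectory log-likelihood (nats) after each accepted stage,
#'   non-decreasing within tolerance inside each stage. When the exponential
#'   nonlinearity is replaced by the 7-knot spline the model family changes,
#'   so Z may step once at the boundary (on data whose true nonlinearity is
#'   exactly exponential the restricted spline family can sit slightly
#'   below the exponential optimum).
#' @slot splineStageAt index in \code{zTrajectory} of the first spline-stage
#'   value (0 when the fit stopped after the exponential stage).
#' @slot converged whether the stopping tolerance was reached.
#' @slot nIterations outer iterations performed in the spline stage.
#' @exportClass FitResult
setClass("FitResult",
  representation(cell = "LNPCell", zTrajectory = "numeric",
                 splineStageAt = "integer", converged = "logical",
                 nIterations = "integer"),
  validity = function(object) {
    z <- object@zTrajectory
    bad <- which(diff(z) < -1e-6 * max(1, abs(z[1])))
    if (length(setdiff(bad + 1L, object@splineStageAt)))
      "zTrajectory must be non-decreasing within each stage" else TRUE
  })

#' DecodeReport: maximum-likelihood decoding performance
#'
#' @slot perStimulus fraction of correct trials per presented stimulus.
#' @slot overall overall fraction correct.
#' @slot nTrials decoded trials per stimulus.
#' @slot nCells population size used.
#' @slot options decoded option labels.
#' @slot tieRate fraction of trials with tied maximum likelihood (broken by
#'   lowest option index).
#' @exportClass DecodeReport
setClass("DecodeReport",
  representation(perStimulus = "numeric", overall = "numeric",
                 nTrials = "numeric", nCells = "integer",
                 options = "character", tieRate = "numeric"),
  validity = function(object) {
    ok <- all(object@perStimulus >= 0 & object@perStimulus <= 1) &&
      object@overall >= 0 && object@overall <= 1
    if (!ok) "fractions correct must lie in [0, 1]" else TRUE
  })

#' PsychometricCurve: 2AFC performance versus contrast
#'
#' Fraction of correct present/absent decisions as a function of grating
#' contrast at one temporal frequency, with the 75%-correct contrast
#' threshold and its reciprocal, the contrast sensitivity.
#'
#' @slot temporalFreq grating temporal frequency (Hz).
#' @slot contrasts contrast grid (fractions, descending).
#' @slot fractionCorrect fraction correct at each contrast.
#' @slot threshold lowest contrast with >= 75% correct (NA if never reached).
#' @slot sensitivity 1 / threshold (NA if threshold undefined).
#' @exportClass PsychometricCurve
setClass("PsychometricCurve",
  representation(temporalFreq = "numeric", contrasts = "numeric",
                 fractionCorrect = "numeric", threshold = "numeric",
                 sensitivity = "numeric"))
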