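#' Raised-cosine temporal basis on a log-stretched time axis
#'
#' Builds the standard bank of raised-cosine bumps used to parameterize
#' retinal temporal filters: with \eqn{\phi(t) = \log(t + stretch)} and peak
#' centers \eqn{c_j} evenly spaced in \eqn{\phi} with spacing \eqn{\delta},
#' \deqn{b_j(t) = (1 + \cos(\pi \, clip((\phi(t) - c_j)/(2\delta), -1, 1)))/2,}
#' the standard half-width of two peak spacings, so adjacent bumps overlap
#' and every time bin is covered.
#' The log stretch packs narrow bumps at short latencies and broad ones at
#' long latencies. Each basis function is evaluated at the bin centers and
#' rescaled to peak amplitude 1 on the grid; rows are linearly independent.
#' The default 10 functions on 18 bins of 67 ms span 1.2 s.
#'
#' @param nBasis number of basis functions (<= nBins).
#' @param nBins number of time bins.
#' @param binWidth bin width in seconds.
#' @param stretch log-stretch constant in seconds; smaller values concentrate
#'   more basis functions at short latencies.
#' @return a \linkS4class{TemporalBasis}
#' @examples
#' b <- raisedCosineBasis()
#' dim(b@basis)  # 10 x 18
#' @export
raisedCosineBasis <- function(nBasis = 10, nBins = 18, binWidth = 0.067,
                              stretch = 0.05) {
  stopifnot(nBasis >= 1, nBasis <= nBins, binWidth > 0, stretch > 0)
  tt <- (seq_len(nBins) - 0.5) * binWidth
  phi <- log(tt + stretch)
  centers <- seq(phi[1], phi[nBins], length.out = nBasis)
  delta <- if (nBasis > 1) centers[2] - centers[1] else diff(range(phi)) / 2
  B <- matrix(0, nBasis, nBins)
  for (j in seq_len(nBasis)) {
    z <- pmin(pmax((phi - centers[j]) / (2 * delta), -1), 1)
    B[j, ] <- 0.5 * (1 + cos(pi * z))
  }
  mx <- apply(B, 1, max)
  if (any(mx <= 0))
    stop("a basis function vanishes on the bin grid; increase stretch")
  B <- B / mx                 # peak amplitude exactly 1 on the grid
  new("TemporalBasis", basis = B, binWidth = binWidth, stretch = stretch)
}

#' Exponential nonlinearity
#'
#' \eqn{N(g) = \max(\exp(gain \cdot g + offset), rateFloor)} in spikes/s.
#' The exponential-Poisson combination makes the spike-train log-likelihood
#' concave in the filter parameters, which is why fitting starts here.
#'
#' @param gain,offset exponential parameters.
#' @param rateFloor minimum rate (spikes/s).
#' @return a \linkS4class{Nonlinearity}
#' @export
exponentialNonlinearity <- function(gain = 1, offset = 0, rateFloor = 1e-3) {
  new("Nonlinearity", kind = "exponential", gain = gain, offset = offset,
      knots = numeric(0), values = numeric(0), rateFloor = rateFloor)
}

#' Cubic-spline nonlinearity
#'
#' An interpolating natural cubic spline through (knot, value) pairs, with
#' linear extrapolation beyond the outer knots, clamped below at
#' \code{rateFloor}. The fitted nonlinearity of an LNP model uses 7 knots
#' spaced evenly over the range of the training generator signal.
#'
#' @param knots strictly increasing knot locations (generator-signal units).
#' @param values rates (spikes/s) at the knots.
#' @param rateFloor minimum rate (spikes/s).
#' @return a \linkS4class{Nonlinearity}
#' @export
splineNonlinearity <- function(knots, values, rateFloor = 1e-3) {
  new("Nonlinearity", kind = "cubic_spline", gain = NA_real_,
      offset = NA_real_, knots = knots, values = values,
      rateFloor = rateFloor)
}

#' Evaluate a nonlinearity on generator-signal values
#'
#' NA inputs (invalid warm-up bins) propagate as NA. A non-finite output for
#' a finite input is an error naming the offending bin.
#'
#' @param nl a \linkS4class{Nonlinearity}.
#' @param g numeric vector of generator-signal values.
#' @return firing rates in spikes/s, \code{>= nl@rateFloor}.
#' @export
evalNonlinearity <- function(nl, g) {
  out <- rep(NA_real_, length(g))
  ok <- !is.na(g)
  if (any(ok)) {
    out[ok] <- if (nl@kind == "exponential")
      exp(nl@gain * g[ok] + nl@offset)
    else
      splinefun(nl@knots, nl@values, method = "natural")(g[ok])
    bad <- ok & !is.finite(out)
    if (any(bad))
      stop(sprintf("nonlinearity produced a non-finite rate at bin %d (g = %.4g)",
                   which(bad)[1], g[which(bad)[1]]))
    out[ok] <- pmax(out[ok], nl@rateFloor)
  }
  out
}

#' Construct an LNP model cell
#'
#' @param spatialWeights 10 x 10 numeric matrix of spatial filter weights
#'   (\code{[row, column]}).
#' @param temporalCoeffs coefficients on the rows of \code{basis}.
#' @param nonlinearity a \linkS4class{Nonlinearity}.
#' @param rfCenter integer (row, column) receptive-field center; the spatial
#'   patch covers rows/columns \code{center - 4 .. center + 5}.
#' @param basis a \linkS4class{TemporalBasis}.
#' @param polarity "ON", "OFF" or "untyped" (metadata).
#' @param cellId identifier.
#' @return an \linkS4class{LNPCell}
#' @export
lnpCell <- function(spatialWeights, temporalCoeffs,
                    nonlinearity = exponentialNonlinearity(),
                    rfCenter = c(5L, 5L), basis = raisedCosineBasis(),
                    polarity = "untyped", cellId = "cell") {
  new("LNPCell", rfCenter = as.integer(rfCenter),
      spatialWeights = spatialWeights, temporalCoeffs = temporalCoeffs,
      basis = basis, nonlinearity = nonlinearity, polarity = polarity,
      cellId = cellId)
}

patchIndices <- function(cell, dims) {
  rows <- cell@rfCenter[1] + (-4L:5L)
  cols <- cell@rfCenter[2] + (-4L:5L)
  if (min(rows) < 1L || max(rows) > dims[2] || min(cols) < 1L ||
      max(cols) > dims[3])
    stop(sprintf("10x10 patch at RF center (%d, %d) falls outside the %dx%d movie",
                 cell@rfCenter[1], cell@rfCenter[2], dims[2], dims[3]))
  list(rows = rows, cols = cols)
}

# Extract the 10x10 patch as a frames x 100 matrix (pixels column-major in
# (row, col), matching as.vector(spatialWeights)).
patchMatrix <- function(cell, movie) {
  d <- dim(movie@frames)
  px <- patchIndices(cell, d)
  x <- movie@frames[, px$rows, px$cols, drop = FALSE]
  dim(x) <- c(d[1], 100L)
  x
}

# Causal FIR filtering of each column of X with taps f (tap 1 = current
# sample); the first length(f) - 1 output samples are NA.
filterColumns <- function(X, f) {
  out <- stats::filter(X, f, method = "convolution", sides = 1)
  matrix(as.numeric(out), nrow = nrow(X))
}

#' Generator signal of an LNP cell for a movie
#'
#' Spatiotemporal convolution of the cell's separable filter with the movie:
#' \eqn{g(t) = \sum_\tau \sum_p spatial_p \, temporal_\tau \, s(p, t - \tau)},
#' one value per frame bin. Bins with incomplete stimulus history (the first
#' 1.2 s, i.e. nBins - 1 frames) are returned as NA rather than silently
#' zero-padded.
#'
#' @param cell an \linkS4class{LNPCell}; the movie frame duration must match
#'   the cell's basis bin width (15 Hz frames for 67 ms bins) within 2%.
#' @param movie a \linkS4class{StimulusMovie} covering the 10x10 patch.
#' @return numeric vector of generator-signal values, NA during warm-up.
#' @export
linearDrive <- function(cell, movie) {
  fdur <- 1 / movie@frameRate
  if (abs(fdur - cell@basis@binWidth) > 0.02 * cell@basis@binWidth)
    stop(sprintf("movie frame duration %.4g s does not match basis bin width %.4g s",
                 fdur, cell@basis@binWidth))
  S <- patchMatrix(cell, movie)
  f <- temporalFilter(cell)
  as.vector(filterColumns(S, f) %*% as.vector(cell@spatialWeights))
}

#' Firing rate of an LNP cell for a movie
#'
#' Applies the cell's nonlinearity to the generator signal:
#' \eqn{\lambda(t) = \max(N(g(t)), rateFloor)} in spikes/s per frame bin.
#' Warm-up bins are NA.
#'
#' @inheritParams linearDrive
#' @return numeric vector of rates (spikes/s), NA during warm-up.
#' @export
firingRate <- function(cell, movie) {
  evalNonlinearity(cell@nonlinearity, linearDrive(cell, movie))
}

#' Sample inhomogeneous-Poisson spike trains from a rate series
#'
#' Per trial and per bin the spike count is Poisson with mean
#' \eqn{\lambda(t) \Delta t}; spike times are placed uniformly within their
#' bin. NA rate bins (warm-up) produce no spikes. Identical seeds give
#' identical rasters.
#'
#' @param rate numeric vector of rates in spikes/s (one per bin; NAs allowed).
#' @param nTrials number of independent trials.
#' @param binWidth bin width in seconds.
#' @param seed RNG seed.
#' @param cellId identifier for the raster.
#' @return a \linkS4class{SpikeRaster}
#' @export
sampleSpikes <- function(rate, nTrials = 1, binWidth = 1/15, seed = NULL,
                         cellId = "cell") {
  stopifnot(nTrials >= 1, binWidth > 0)
  if (any(rate < 0, na.rm = TRUE)) stop("rates must be non-negative")
  lam <- ifelse(is.na(rate), 0, rate) * binWidth
  nb <- length(rate)
  starts <- (seq_len(nb) - 1) * binWidth
  trials <- withSeed(seed, lapply(seq_len(nTrials), function(i) {
    n <- rpois(nb, lam)
    tot <- sum(n)
    if (!tot) return(numeric(0))
    sort(rep(starts, n) + runif(tot) * binWidth)
  }))
  new("SpikeRaster", trials = trials, duration = nb * binWidth,
      cellId = cellId)
}
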