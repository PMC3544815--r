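newStimulusMovie <- function(frames, frameRate, degPerPixel, meanLuminance,
                             rmsContrast) {
  new("StimulusMovie", frames = frames, frameRate = frameRate,
      degPerPixel = degPerPixel, meanLuminance = meanLuminance,
      rmsContrast = rmsContrast)
}

#' Uniform gray movie
#'
#' Every frame uniformly at \code{meanLuminance}; the separator and
#' adaptation stimulus.
#'
#' @param meanLuminance luminance value of every pixel.
#' @param duration duration in seconds.
#' @param width,height geometry in pixels.
#' @param degPerPixel degrees of visual angle per pixel.
#' @param frameRate frames per second.
#' @return a \linkS4class{StimulusMovie}
#' @export
makeGray <- function(meanLuminance = 1, duration = 1/3, width = 32,
                     height = 32, degPerPixel = 2.16, frameRate = 15) {
  nF <- round(duration * frameRate)
  newStimulusMovie(array(meanLuminance, c(nF, height, width)), frameRate,
                   degPerPixel, meanLuminance, 0)
}

#' Drifting sine-wave grating
#'
#' Luminance \eqn{m (1 + c \sin(2\pi(w x - f t)))} drifting along the
#' horizontal (column) axis, with phase 0 at t = 0, x = 0. Over a whole
#' number of temporal cycles the mean equals \code{meanLuminance}.
#'
#' @param temporalFreq drift temporal frequency in Hz (> 0).
#' @param spatialFreq spatial frequency in cycles/degree (> 0, at most the
#'   pixel-grid Nyquist limit \code{0.5 / degPerPixel}).
#' @param contrast Michelson contrast in [0, 1].
#' @param meanLuminance mean luminance (arbitrary linear units).
#' @param duration duration in seconds.
#' @param width,height geometry in pixels.
#' @param degPerPixel degrees of visual angle per pixel.
#' @param frameRate frames per second.
#' @return a \linkS4class{StimulusMovie}
#' @examples
#' g <- makeDriftingGrating(2, 0.058, contrast = 1, duration = 1)
#' nFrames(g)  # 15 frames at 15 Hz
#' @export
makeDriftingGrating <- function(temporalFreq, spatialFreq, contrast = 1,
                                meanLuminance = 1, duration = 1, width = 32,
                                height = 32, degPerPixel = 2.16,
                                frameRate = 15) {
  stopifnot(temporalFreq > 0, spatialFreq > 0, duration > 0,
            contrast >= 0, contrast <= 1)
  wpx <- spatialFreq * degPerPixel          # cycles per pixel
  if (wpx > 0.5 + 1e-12)
    stop(sprintf(paste0("spatial frequency %.4g cyc/deg exceeds the Nyquist ",
                        "limit %.4g cyc/deg of the pixel grid (%.4g deg/pixel)"),
                 spatialFreq, 0.5 / degPerPixel, degPerPixel))
  nF <- round(duration * frameRate)
  tt <- (seq_len(nF) - 1L) / frameRate
  xx <- seq_len(width) - 1L
  # phase(t, x) = 2*pi*(wpx*x - f*t); frames constant along rows (y)
  plane <- meanLuminance *
    (1 + contrast * sin(2 * pi * outer(-temporalFreq * tt, wpx * xx, `+`)))
  fr <- array(0, c(nF, height, width))
  for (y in seq_len(height)) fr[, y, ] <- plane
  newStimulusMovie(fr, frameRate, degPerPixel, meanLuminance,
                   meanLuminance * contrast / sqrt(2))
}

#' Binary spatiotemporal white noise
#'
#' Each pixel in each frame independently takes \code{meanLuminance +
#' amplitude} or \code{meanLuminance - amplitude} with probability 1/2, so the
#' RMS contrast is \code{amplitude}. Identical seeds give bit-identical
#' movies.
#'
#' @param meanLuminance mean luminance; must be >= \code{amplitude} so the
#'   movie stays non-negative.
#' @param amplitude half-range of the binary flicker (luminance units).
#' @param duration duration in seconds.
#' @param width,height geometry in pixels.
#' @param degPerPixel degrees of visual angle per pixel.
#' @param frameRate frames per second.
#' @param seed RNG seed.
#' @return a \linkS4class{StimulusMovie}
#' @export
makeBinaryWhiteNoise <- function(meanLuminance = 1, amplitude = 0.16,
                                 duration = 10, width = 32, height = 32,
                                 degPerPixel = 2.16, frameRate = 15,
                                 seed = NULL) {
  stopifnot(duration > 0, amplitude >= 0)
  if (amplitude > meanLuminance)
    stop("amplitude must not exceed meanLuminance (luminance must stay >= 0)")
  nF <- round(duration * frameRate)
  fr <- withSeed(seed,
    array(meanLuminance + amplitude * (2 * (runif(nF * height * width) < 0.5) - 1),
          c(nF, height, width)))
  newStimulusMovie(fr, frameRate, degPerPixel, meanLuminance, amplitude)
}

# fft frequencies in cycles/sample for n samples (DC first, then positive,
# then negative), matching R's fft ordering.
fftFreq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

#' Natural-like movie with power-law spectra
#'
#' Spectral synthesis of a Gaussian luminance field whose temporal power
#' spectrum falls as \eqn{1/f^{te}} and whose spatial power spectrum falls as
#' \eqn{1/w^{se}} in radial spatial frequency (separable space-time power
#' laws, independent uniform phases). The field is affinely rescaled to the
#' stated mean and RMS contrast and clipped at zero luminance; if more than 1%
#' of the pixel mass is clipped a warning is issued. The defaults match the
#' spectra of natural time-varying scenes (temporal exponent 2.04, spatial
#' exponent 2.09).
#'
#' @param temporalExponent,spatialExponent power-law exponents (>= 0).
#' @param meanLuminance mean luminance (arbitrary linear units).
#' @param rmsContrast target luminance standard deviation.
#' @param duration duration in seconds.
#' @param width,height geometry in pixels.
#' @param degPerPixel degrees of visual angle per pixel.
#' @param frameRate frames per second.
#' @param seed RNG seed.
#' @return a \linkS4class{StimulusMovie}
#' @seealso \code{\link{estimateSpectrumExponent}} to check the realized
#'   spectral slopes.
#' @export
makeNaturalMovie <- function(temporalExponent = 2.04, spatialExponent = 2.09,
                             meanLuminance = 1, rmsContrast = 0.16,
                             duration = 10, width = 32, height = 32,
                             degPerPixel = 2.16, frameRate = 15, seed = NULL) {
  stopifnot(temporalExponent >= 0, spatialExponent >= 0, duration > 0,
            rmsContrast >= 0, meanLuminance > 0)
  nF <- round(duration * frameRate)
  ft <- abs(fftFreq(nF))
  fy <- fftFreq(height)
  fx <- fftFreq(width)
  w <- sqrt(outer(fy^2, fx^2, `+`))               # radial spatial frequency
  Pt <- ifelse(ft > 0, ft^(-temporalExponent), 0)
  Ps <- ifelse(w > 0, w^(-spatialExponent), 0)
  P <- array(0, c(nF, height, width))
  for (i in seq_len(nF)) P[i, , ] <- Pt[i] * Ps    # zero where f == 0 or w == 0
  x <- withSeed(seed, {
    Z <- fft(array(rnorm(nF * height * width), c(nF, height, width)))
    mag <- Mod(Z)
    mag[mag == 0] <- 1
    Re(fft(sqrt(P) * (Z / mag), inverse = TRUE)) / (nF * height * width)
  })
  s <- sd(as.vector(x))
  if (s > 0) x <- x * (rmsContrast / s)
  fr <- meanLuminance + x
  clipped <- mean(fr < 0)
  if (clipped > 0.01)
    warning(sprintf("rms contrast %.3g clips %.2f%% of the luminance mass at 0",
                    rmsContrast, 100 * clipped))
  fr[fr < 0] <- 0
  newStimulusMovie(fr, frameRate, degPerPixel, meanLuminance, rmsContrast)
}

#' Build a labeled stimulus ensemble
#'
#' @param segments named list of \linkS4class{StimulusMovie} segments of equal
#'   duration and geometry; names are the stimulus labels.
#' @param grayDuration duration of the gray separator inserted between
#'   segments when a stream is assembled (seconds; the 333 ms default rounds
#'   to 5 frames at 15 Hz).
#' @param prior prior probability per label; uniform by default.
#' @return a \linkS4class{StimulusEnsemble}
#' @export
stimulusEnsemble <- function(segments, grayDuration = 1/3, prior = NULL) {
  if (is.null(prior)) prior <- rep(1 / length(segments), length(segments))
  names(prior) <- names(segments)
  segDur <- duration(segments[[1]])
  new("StimulusEnsemble", segments = segments, prior = prior,
      segDuration = segDur, grayDuration = grayDuration)
}

#' Ensemble of natural-like movie snippets
#'
#' Independent natural-movie segments (see \code{\link{makeNaturalMovie}}),
#' labeled \code{nat01, nat02, ...}; the standard 30-snippet set has stimulus
#' entropy log2(30) = 4.9 bits under the uniform prior.
#'
#' @param nStim number of snippets.
#' @param duration segment duration (seconds).
#' @param seed master seed; snippet i uses a seed derived from it.
#' @param ... further arguments to \code{\link{makeNaturalMovie}}.
#' @return a \linkS4class{StimulusEnsemble}
#' @export
makeNaturalEnsemble <- function(nStim = 30, duration = 1, seed = 1, ...) {
  labs <- sprintf("nat%02d", seq_len(nStim))
  segs <- lapply(seq_len(nStim), function(i)
    makeNaturalMovie(duration = duration,
                     seed = moduleSeed(seed, paste0("natseg", i)), ...))
  names(segs) <- labs
  stimulusEnsemble(segs)
}

#' Ensemble of drifting gratings varying in temporal or spatial frequency
#'
#' @param temporalFreqs,spatialFreqs exactly one of the two must have length
#'   > 1; the other (scalar) is held fixed across segments.
#' @param contrast grating contrast.
#' @param duration segment duration (seconds).
#' @param ... further arguments to \code{\link{makeDriftingGrating}}.
#' @return a \linkS4class{StimulusEnsemble}
#' @export
makeGratingEnsemble <- function(temporalFreqs = 2, spatialFreqs = 0.058,
                                contrast = 1, duration = 1, ...) {
  if (length(temporalFreqs) > 1 && length(spatialFreqs) > 1)
    stop("vary only one of temporalFreqs and spatialFreqs")
  if (length(temporalFreqs) > 1) {
    labs <- sprintf("tf%05.2fHz", temporalFreqs)
    segs <- lapply(temporalFreqs, function(f)
      makeDriftingGrating(f, spatialFreqs, contrast, duration = duration, ...))
  } else {
    labs <- sprintf("sf%06.4fcpd", spatialFreqs)
    segs <- lapply(spatialFreqs, function(w)
      makeDriftingGrating(temporalFreqs, w, contrast, duration = duration, ...))
  }
  names(segs) <- labs
  stimulusEnsemble(segs)
}

#' Stimulus entropy of an ensemble
#'
#' Shannon entropy of the ensemble's label prior in bits; for the standard
#' uniform 30-snippet set this is log2(30) = 4.9 bits, the ceiling on the
#' stimulus information any response can carry.
#'
#' @param ensemble a \linkS4class{StimulusEnsemble}.
#' @return entropy in bits.
#' @export
stimulusEntropy <- function(ensemble) {
  p <- ensemble@prior[ensemble@prior > 0]
  -sum(p * log2(p))
}

#' Assemble an ensemble into a presentation stream
#'
#' Concatenates segment, gray, segment, gray, ... in the stated order
#' (repeated \code{repeats} times), with gray frames at the segments' mean
#' luminance, and returns the movie together with a per-frame label track
#' (segment label or \code{"GRAY"}). Gray durations are rounded to whole
#' frames (333 ms at 15 Hz becomes 5 frames).
#'
#' @param ensemble a \linkS4class{StimulusEnsemble}.
#' @param order character vector of segment labels; defaults to the
#'   ensemble's own order. May be empty, giving an empty stream.
#' @param repeats number of repetitions of \code{order}.
#' @return a \linkS4class{StimulusStream}
#' @export
assembleStream <- function(ensemble, order = NULL, repeats = 1) {
  stopifnot(is(ensemble, "StimulusEnsemble"), repeats >= 1)
  if (is.null(order)) order <- names(ensemble@segments)
  if (!all(order %in% names(ensemble@segments)))
    stop("unknown labels in order: ",
         paste(setdiff(order, names(ensemble@segments)), collapse = ", "))
  ref <- ensemble@segments[[1]]
  d <- dim(ref@frames)
  fps <- ref@frameRate
  nGray <- round(ensemble@grayDuration * fps)
  order <- rep(order, repeats)
  if (!length(order)) {
    mov <- newStimulusMovie(array(0, c(0, d[2], d[3])), fps, ref@degPerPixel,
                            ref@meanLuminance, 0)
    return(new("StimulusStream", movie = mov, labels = character(0)))
  }
  gray <- array(ref@meanLuminance, c(nGray, d[2], d[3]))
  pieces <- vector("list", 2L * length(order))
  labels <- vector("list", 2L * length(order))
  for (i in seq_along(order)) {
    seg <- ensemble@segments[[order[i]]]@frames
    pieces[[2L * i - 1L]] <- seg
    pieces[[2L * i]] <- gray
    labels[[2L * i - 1L]] <- rep(order[i], dim(seg)[1])
    labels[[2L * i]] <- rep("GRAY", nGray)
  }
  total <- sum(vapply(pieces, function(p) dim(p)[1], numeric(1)))
  fr <- array(0, c(total, d[2], d[3]))
  at <- 0L
  for (p in pieces) {
    n <- dim(p)[1]
    if (n) fr[at + seq_len(n), , ] <- p
    at <- at + n
  }
  mov <- newStimulusMovie(fr, fps, ref@degPerPixel, ref@meanLuminance,
                          ref@rmsContrast)
  new("StimulusStream", movie = mov, labels = unlist(labels))
}
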