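#' Estimate the power-law exponent of a movie's spectrum
#'
#' Averages the periodogram of the (mean-subtracted) movie along the chosen
#' axis and fits a least-squares line to log power versus log frequency over
#' the fit band; returns the negative slope, i.e. the exponent of an assumed
#' \eqn{1/f^{exponent}} power law.
#'
#' For \code{axis = "time"} the per-pixel temporal periodogram is averaged
#' over pixels and frequencies are in Hz. For \code{axis = "space"} the 2-D
#' spatial periodogram is averaged over frames, each Fourier component enters
#' the fit at its radial frequency (cycles/degree), and components beyond the
#' axis Nyquist frequency are discarded.
#'
#' @param movie a \linkS4class{StimulusMovie} with at least 64 samples along
#'   the chosen axis.
#' @param axis "time" or "space".
#' @param fitBand optional c(min, max) frequency range (Hz or cycles/degree)
#'   over which to fit; defaults to all resolvable non-zero frequencies below
#'   the Nyquist limit. Must intersect the resolvable range.
#' @return the estimated exponent (negative log-log slope), with the fitted
#'   frequencies and powers attached as attributes \code{"freq"} and
#'   \code{"power"}.
#' @examples
#' mov <- makeNaturalMovie(duration = 512 / 15, width = 16, height = 16, seed = 1)
#' estimateSpectrumExponent(mov, "time")
#' @export
estimateSpectrumExponent <- function(movie, axis = c("time", "space"),
                                     fitBand = NULL) {
  axis <- match.arg(axis)
  fr <- movie@frames
  d <- dim(fr)
  if (axis == "time") {
    if (d[1] < 64) stop("need >= 64 samples along the time axis")
    X <- matrix(fr, nrow = d[1])            # time x pixel
    X <- sweep(X, 2, colMeans(X))
    pw <- rowMeans(Mod(mvfft(X))^2) / d[1]
    fq <- abs(fftFreq(d[1])) * movie@frameRate
    keep <- fq > 0 & fq < 0.5 * movie@frameRate - 1e-12
    fq <- fq[keep]; pw <- pw[keep]
  } else {
    if (min(d[2], d[3]) < 64) stop("need >= 64 samples along each spatial axis")
    nyq <- 0.5 / movie@degPerPixel
    fy <- fftFreq(d[2]) / movie@degPerPixel
    fx <- fftFreq(d[3]) / movie@degPerPixel
    w <- sqrt(outer(fy^2, fx^2, `+`))
    acc <- matrix(0, d[2], d[3])
    for (i in seq_len(d[1])) {
      fm <- fr[i, , ]
      acc <- acc + Mod(fft(fm - mean(fm)))^2
    }
    pw <- as.vector(acc / (d[1] * d[2] * d[3]))
    fq <- as.vector(w)
    keep <- fq > 0 & fq < nyq - 1e-12
    fq <- fq[keep]; pw <- pw[keep]
  }
  if (!is.null(fitBand)) {
    stopifnot(length(fitBand) == 2L, fitBand[1] < fitBand[2])
    inband <- fq >= fitBand[1] & fq <= fitBand[2]
    if (sum(inband) < 3L)
      stop("fitBand lies outside the resolvable frequencies")
    fq <- fq[inband]; pw <- pw[inband]
  }
  pos <- pw > 0
  fit <- lm(log(pw[pos]) ~ log(fq[pos]))
  structure(-unname(coef(fit)[2]), freq = fq, power = pw)
}
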