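# Biphasic temporal impulse response (difference of gamma-like lobes)
# evaluated at the basis bin centers; tau1 = time to peak of the excitatory
# lobe, k = relative strength of the rebound lobe.
biphasicKernel <- function(tt, tau1, k, tau2 = 1.8 * tau1, n = 5) {
  lobe <- function(tau) (tt / tau)^n * exp(n * (1 - tt / tau))
  lobe(tau1) - k * lobe(tau2)
}

# Difference-of-Gaussians spatial profile on the 10x10 patch, centered
# between pixels (5.5, 5.5); surround strength in [0, 1), 1 = balanced.
dogPatch <- function(sdCenter, surround, sdSurround = 2 * sdCenter) {
  xy <- (1:10) - 5.5
  d2 <- outer(xy^2, xy^2, `+`)
  exp(-d2 / (2 * sdCenter^2)) -
    surround * (sdCenter^2 / sdSurround^2) * exp(-d2 / (2 * sdSurround^2))
}

#' Generate a ground-truth synthetic LNP population
#'
#' Creates ON- and OFF-like model cells with center-surround
#' difference-of-Gaussians spatial filters (sign of the center set by
#' polarity), biphasic temporal filters projected onto the raised-cosine
#' basis, and exponential nonlinearities. The condition presets are
#' illustrative parameter families, not measured values: "photopic" cells
#' have fast, strongly biphasic (transient) temporal filters, "scotopic"
#' cells slower, more sustained ones. Filters are scaled so the generator
#' signal has unit standard deviation for a white-noise stimulus of RMS
#' contrast \code{designContrast}, and the exponential offset is set so the
#' mean rate under that stimulus is about \code{meanRate} spikes/s.
#' Deterministic under \code{seed}.
#'
#' @param nCells number of cells (>= 1).
#' @param fracOn fraction of ON cells; the first \code{round(nCells *
#'   fracOn)} cells are ON, the rest OFF.
#' @param condition "photopic" or "scotopic" temporal-filter preset.
#' @param fieldDim (rows, columns) of the stimulus field the receptive
#'   fields live in.
#' @param layout "grid" (deterministic centers) or "jitter" (random valid
#'   centers).
#' @param meanRate target mean firing rate (spikes/s) under the design
#'   stimulus.
#' @param designContrast RMS contrast of the white-noise stimulus the gain
#'   is calibrated for.
#' @param basis \linkS4class{TemporalBasis} shared by the population.
#' @param seed RNG seed.
#' @return list of \linkS4class{LNPCell}
#' @examples
#' pop <- makePopulation(4, seed = 1)
#' vapply(pop, function(cc) cc@polarity, character(1))
#' @export
makePopulation <- function(nCells, fracOn = 0.5,
                           condition = c("photopic", "scotopic"),
                           fieldDim = c(16L, 16L), layout = c("grid", "jitter"),
                           meanRate = 10, designContrast = 0.16,
                           basis = raisedCosineBasis(), seed = NULL) {
  condition <- match.arg(condition)
  layout <- match.arg(layout)
  stopifnot(nCells >= 1, fracOn >= 0, fracOn <= 1,
            all(fieldDim >= 10))
  nOn <- round(nCells * fracOn)
  polar <- c(rep("ON", nOn), rep("OFF", nCells - nOn))
  validR <- 5:(fieldDim[1] - 5L)
  validC <- 5:(fieldDim[2] - 5L)
  tt <- (seq_len(ncol(basis@basis)) - 0.5) * basis@binWidth
  B <- basis@basis
  withSeed(seed, lapply(seq_len(nCells), function(i) {
    if (layout == "grid") {
      ctr <- c(validR[(i - 1) %% length(validR) + 1],
               validC[((i - 1) %/% length(validR)) %% length(validC) + 1])
    } else {
      ctr <- c(sample(validR, 1), sample(validC, 1))
    }
    tau1 <- if (condition == "photopic") runif(1, 0.07, 0.10)
            else runif(1, 0.14, 0.19)
    k <- if (condition == "photopic") runif(1, 0.6, 0.9)
         else runif(1, 0.2, 0.45)
    p <- biphasicKernel(tt, tau1, k)
    a <- qr.solve(t(B), p)
    a <- a / sqrt(sum(a^2))
    sp <- dogPatch(runif(1, 1.0, 1.5), runif(1, 0.55, 0.75))
    if (polar[i] == "OFF") sp <- -sp
    f <- as.vector(a %*% B)
    nrm <- sqrt(sum(outer(f, as.vector(sp))^2))
    sp <- sp / (nrm * designContrast)      # unit generator-signal s.d.
    g0 <- sum(f) * sum(sp)                 # DC drive at unit mean luminance
    lnpCell(sp, a,
            exponentialNonlinearity(gain = 1,
                                    offset = log(meanRate) - 0.5 - g0),
            rfCenter = ctr, basis = basis, polarity = polar[i],
            cellId = sprintf("%s%02d", tolower(polar[i]), i))
  }))
}
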