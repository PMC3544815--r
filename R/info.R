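#' Log-probability of a binned response under Poisson intensities
#'
#' \eqn{\log p(r|s) = \sum_k \log Pois(n_k; u_k)} in nats, with zero
#' intensities floored at 1e-9 counts/bin so the log stays finite.
#'
#' @param counts non-negative integer vector of bin counts.
#' @param u mean counts per bin (same length).
#' @param floor intensity floor replacing zeros.
#' @return log probability in nats.
#' @examples
#' responseLogProb(0, 1)        # -1
#' responseLogProb(c(0, 0), c(1, 2))  # -3
#' @export
responseLogProb <- function(counts, u, floor = 1e-9) {
  stopifnot(length(counts) == length(u))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(u < 0)) stop("intensities must be non-negative")
  sum(dpois(counts, pmax(u, floor), log = TRUE))
}

checkPrior <- function(prior, nS) {
  if (is.null(prior)) prior <- rep(1 / nS, nS)
  stopifnot(length(prior) == nS, abs(sum(prior) - 1) < 1e-8, all(prior >= 0))
  prior
}

#' Mutual information under the Poisson response model
#'
#' Estimates \eqn{I(S; R) = \langle \log_2 [p(r|s) / p(r)] \rangle} in bits,
#' with p(r|s) the independent-Poisson likelihood of the rate profiles and
#' \eqn{p(r) = \sum_{s'} p(s') p(r|s')} marginalized exactly over the
#' stimulus set. The outer average is a Monte-Carlo sum over (s, r) pairs
#' drawn from their joint distribution -- except that when the (truncated)
#' response outcome space is small enough the sum is enumerated exactly,
#' which doubles as the brute-force oracle for the sampler. Responses are
#' truncated at the 1 - 1e-6 Poisson quantile for enumeration.
#'
#' @param profiles a \linkS4class{RateProfiles}.
#' @param prior stimulus prior (uniform when NULL).
#' @param mcSamples Monte-Carlo sample count (a warning is issued below
#'   1000).
#' @param seed RNG seed for the sampler.
#' @param method "auto" (exact when the outcome space has at most
#'   \code{maxExactPoints} points, else Monte-Carlo), "exact" or "mc".
#' @param maxExactPoints enumeration budget.
#' @return an \linkS4class{MIResult} (bits)
#' @export
mutualInformationPoisson <- function(profiles, prior = NULL,
                                     mcSamples = 50000, seed = NULL,
                                     method = c("auto", "exact", "mc"),
                                     maxExactPoints = 1e6) {
  method <- match.arg(method)
  u <- pmax(profiles@u, 1e-9)
  nS <- nrow(u); K <- ncol(u)
  prior <- checkPrior(prior, nS)
  caps <- vapply(seq_len(K), function(k) qpois(1 - 1e-6, max(u[, k])),
                 numeric(1))
  nPoints <- prod(caps + 1)
  if (method == "auto")
    method <- if (nPoints <= maxExactPoints) "exact" else "mc"

  if (method == "exact") {
    if (nPoints > maxExactPoints)
      stop(sprintf("outcome space too large to enumerate (%.3g points)", nPoints))
    grid <- as.matrix(expand.grid(lapply(caps, function(cp) 0:cp)))
    # log p(r|s), including the log n! term, for every grid point and stimulus
    lgam <- rowSums(lgamma(grid + 1))
    logp <- grid %*% t(log(u)) - rep(1, nrow(grid)) %o% rowSums(u) - lgam
    logMarg <- rowLogSumExp(sweep(logp, 2, log(prior), `+`))
    I <- 0
    for (s in seq_len(nS)) {
      ps <- exp(logp[, s])
      I <- I + prior[s] * sum(ps * (logp[, s] - logMarg))
    }
    return(new("MIResult", value = I / log(2), estimator = "poisson_exact",
               binWidth = profiles@binWidth, mcSamples = 0, se = NA_real_,
               seed = if (is.null(seed)) NA_real_ else seed,
               debiased = FALSE))
  }

  if (mcSamples < 1000)
    warning("fewer than 1000 Monte-Carlo samples; the estimate will be noisy")
  logu <- log(u)
  sumu <- rowSums(u)
  vals <- withSeed(seed, {
    sIdx <- sample.int(nS, mcSamples, replace = TRUE, prob = prior)
    r <- matrix(rpois(mcSamples * K, u[sIdx, , drop = FALSE]), mcSamples, K)
    # log p(r|s') up to the shared log n! term, which cancels in the ratio
    L <- r %*% t(logu) - rep(1, mcSamples) %o% sumu
    (L[cbind(seq_len(mcSamples), sIdx)] -
       rowLogSumExp(sweep(L, 2, log(prior), `+`))) / log(2)
  })
  new("MIResult", value = mean(vals), estimator = "poisson_mc",
      binWidth = profiles@binWidth, mcSamples = mcSamples,
      se = sd(vals) / sqrt(mcSamples),
      seed = if (is.null(seed)) NA_real_ else seed, debiased = FALSE)
}

# Plug-in quartile MI (bits) of a trial x stimulus x bin count array,
# optionally on a subset of trials: counts are mapped to response levels
# {0, 1, 2, >=3}, level probabilities are estimated empirically per bin, and
# the per-bin informations are summed.
quartilePlugin <- function(cnt, prior, maxCount = 3) {
  nT <- dim(cnt)[1]; nS <- dim(cnt)[2]; K <- dim(cnt)[3]
  lev <- pmin(cnt, maxCount)
  total <- 0
  for (k in seq_len(K)) {
    pls <- vapply(seq_len(nS), function(s)
      tabulate(lev[, s, k] + 1L, nbins = maxCount + 1L) / nT,
      numeric(maxCount + 1L))               # level x stimulus
    pl <- as.vector(pls %*% prior)
    term <- pls * log2(sweep(pls, 1, pl, `/`))
    term[!is.finite(term)] <- 0             # 0 log 0 = 0
    total <- total + sum(sweep(term, 2, prior, `*`))
  }
  total
}

#' Mutual information from empirical response levels (quartile estimator)
#'
#' A model-free alternative to the Poisson estimator: bin counts are divided
#' into four response levels (0, 1, 2, or 3-or-more spikes), the level
#' probabilities per time bin are estimated empirically, and the plug-in
#' information is summed over bins. Because this estimates many response
#' probabilities it carries a positive small-sample bias, so it is paired by
#' default with quadratic-extrapolation debiasing
#' (\code{\link{debiasQuadratic}}): the information is recomputed on random
#' subsamples of trials at fractions 1, 1/2 and 1/4 and extrapolated to
#' infinite data.
#'
#' @param binned a \linkS4class{BinnedResponse} with >= 2 trials (>= 8 per
#'   stimulus recommended).
#' @param prior stimulus prior (uniform when NULL).
#' @param debias apply quadratic-extrapolation debiasing.
#' @param fractions trial fractions used for the extrapolation.
#' @param nResamples random subsamples averaged per fraction < 1.
#' @param seed RNG seed for the subsampling.
#' @return an \linkS4class{MIResult} (bits)
#' @export
mutualInformationQuartile <- function(binned, prior = NULL, debias = TRUE,
                                      fractions = c(1, 0.5, 0.25),
                                      nResamples = 20, seed = NULL) {
  cnt <- binned@counts
  nT <- dim(cnt)[1]
  if (nT < 2) stop("need at least 2 trials per stimulus")
  prior <- checkPrior(prior, dim(cnt)[2])
  iFull <- quartilePlugin(cnt, prior)
  if (!debias)
    return(new("MIResult", value = iFull, estimator = "quartile",
               binWidth = binned@binWidth, mcSamples = 0, se = NA_real_,
               seed = if (is.null(seed)) NA_real_ else seed,
               debiased = FALSE))
  vals <- withSeed(seed, vapply(fractions, function(f) {
    if (f >= 1) return(iFull)
    m <- max(2L, round(f * nT))
    mean(vapply(seq_len(nResamples), function(r) {
      idx <- sample.int(nT, m)
      quartilePlugin(cnt[idx, , , drop = FALSE], prior)
    }, numeric(1)))
  }, numeric(1)))
  iInf <- debiasQuadratic(fractions, vals, nTrials = nT)
  new("MIResult", value = iInf, estimator = "quartile",
      binWidth = binned@binWidth, mcSamples = 0, se = NA_real_,
      seed = if (is.null(seed)) NA_real_ else seed, debiased = TRUE)
}

#' Quadratic-extrapolation debiasing of an information estimate
#'
#' Fits \eqn{I(x) = I_\infty + a x + b x^2} with \eqn{x = 1/(fraction \cdot
#' nTrials)} (the inverse effective sample size) to information values
#' computed on nested data fractions, and returns the extrapolated
#' infinite-data value \eqn{I_\infty}.
#'
#' @param fractions data fractions (must include 1 and at least two smaller
#'   values; >= 3 distinct fractions).
#' @param values information estimates at those fractions.
#' @param nTrials number of trials at fraction 1.
#' @return the debiased value \eqn{I_\infty}.
#' @examples
#' # values lying exactly on I = 2 + x + 0.5 x^2 recover 2
#' debiasQuadratic(c(10, 5, 2.5), 2 + c(0.1, 0.2, 0.4) +
#'                 0.5 * c(0.1, 0.2, 0.4)^2, nTrials = 1)
#' @export
debiasQuadratic <- function(fractions, values, nTrials = 1) {
  stopifnot(length(fractions) == length(values))
  if (length(unique(fractions)) < 3)
    stop("need at least 3 distinct data fractions to fit a quadratic")
  if (max(fractions) < 1) stop("fractions must include the full data (1)")
  x <- 1 / (fractions * nTrials)
  unname(coef(lm(values ~ x + I(x^2)))[1])
}
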