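# Spike counts per frame bin, summed across trials; also reports spikes that
# fell in invalid (warm-up) bins.
frameCounts <- function(raster, nFrames, frameRate) {
  edges <- (0:nFrames) / frameRate
  counts <- matrix(0L, length(raster@trials), nFrames)
  for (i in seq_along(raster@trials)) {
    tt <- raster@trials[[i]]
    if (length(tt))
      counts[i, ] <- tabulate(findInterval(tt, edges, left.open = FALSE,
                                           rightmost.closed = FALSE),
                              nbins = nFrames)
  }
  counts
}

#' Spike-train log-likelihood of an LNP cell
#'
#' The discretized Poisson log-likelihood
#' \deqn{Z = \sum_{bins} [ n \log\lambda - \lambda \Delta t ],}
#' summed over trials, in nats, omitting the parameter-independent
#' \eqn{\log n!} terms. Bins in the 1.2 s warm-up (incomplete convolution
#' history) are excluded; the number of spikes discarded with them is
#' attached as attribute \code{"excludedSpikes"}.
#'
#' @param cell an \linkS4class{LNPCell}.
#' @param movie the \linkS4class{StimulusMovie} the raster responds to.
#' @param raster a \linkS4class{SpikeRaster} whose duration matches the movie.
#' @return log-likelihood in nats (numeric scalar with attribute
#'   \code{"excludedSpikes"}).
#' @export
logLikelihoodLNP <- function(cell, movie, raster) {
  nF <- nFrames(movie)
  if (abs(raster@duration - duration(movie)) > 1e-6)
    stop("raster duration does not match the movie")
  dt <- 1 / movie@frameRate
  lam <- firingRate(cell, movie)
  valid <- !is.na(lam)
  cm <- frameCounts(raster, nF, movie@frameRate)
  N <- colSums(cm)
  R <- length(raster@trials)
  z <- sum(N[valid] * log(lam[valid])) - R * dt * sum(lam[valid])
  structure(z, excludedSpikes = sum(N[!valid]))
}

#' Place spline knots over the generator-signal range
#'
#' Seven (by default) knots evenly spaced on [min(g), max(g)] of the training
#' generator signal, so the spline nonlinearity covers the range of values
#' the linear filter actually produces.
#'
#' @param g generator-signal series (NAs ignored).
#' @param nKnots number of knots (>= 4).
#' @return sorted numeric vector of knot locations.
#' @examples
#' placeKnots(c(-3, 3))  # -3, -2, ..., 3
#' @export
placeKnots <- function(g, nKnots = 7) {
  stopifnot(nKnots >= 4)
  r <- range(g, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] <= r[1])
    stop("degenerate generator signal: constant drive has no range to cover")
  seq(r[1], r[2], length.out = nKnots)
}

#' Fitting configuration
#'
#' @param maxOuterIters maximum outer (spline / filter alternation)
#'   iterations.
#' @param tol convergence tolerance on the change of Z per spike
#'   (nats/spike).
#' @param nKnots number of spline knots.
#' @param useSpline if FALSE, stop after the exponential stage.
#' @param stage1MaxIters maximum coordinate-ascent iterations in the
#'   exponential stage.
#' @param init "sta" (spike-triggered-average initialization) or "random".
#' @param seed seed for random initialization.
#' @return a list of class \code{fitConfig}.
#' @export
fitConfig <- function(maxOuterIters = 50, tol = 1e-6, nKnots = 7,
                      useSpline = TRUE, stage1MaxIters = 30, init = "sta",
                      seed = NULL) {
  stopifnot(tol > 0, nKnots >= 4)
  structure(list(maxOuterIters = maxOuterIters, tol = tol, nKnots = nKnots,
                 useSpline = useSpline, stage1MaxIters = stage1MaxIters,
                 init = match.arg(init, c("sta", "random")), seed = seed),
            class = "fitConfig")
}

# Poisson GLM block step: maximize sum(N * eta - R*dt*exp(eta)) over
# eta = X beta + intercept. Returns list(intercept, beta).
glmBlock <- function(X, N, R, dt) {
  fit <- suppressWarnings(
    glm.fit(cbind(1, X), N, family = poisson(),
            offset = rep(log(R * dt), length(N)),
            control = list(maxit = 100)))
  cf <- coef(fit)
  cf[!is.finite(cf)] <- 0
  list(intercept = cf[1], beta = cf[-1])
}

# Estimate the receptive-field center from the energy of the whitened
# (ridge-decorrelated) spike-triggered average, clamped so the 10x10 patch
# fits. Whitening matters for stimuli with spatial correlations (natural
# movies), where the raw STA of a balanced center-surround filter smears
# into the stimulus covariance.
estimateRfCenter <- function(movie, N, nLags) {
  d <- dim(movie@frames)
  if (d[2] == 10L && d[3] == 10L) return(c(5L, 5L))
  S <- matrix(movie@frames, nrow = d[1])
  S <- sweep(S, 2, colMeans(S))
  Tn <- d[1]
  C <- crossprod(S) / Tn
  R <- chol(C + 0.1 * mean(diag(C)) * diag(ncol(S)))
  energy <- numeric(ncol(S))
  for (lag in 0:(nLags - 1L)) {
    idx <- (1 + lag):Tn
    sta <- crossprod(S[idx - lag, , drop = FALSE], N[idx]) / sum(N)
    energy <- energy + backsolve(R, backsolve(R, sta, transpose = TRUE))^2
  }
  e <- matrix(energy, d[2], d[3])
  # 3x3 box smoothing: a localized RF cluster beats isolated noise peaks
  pad <- rbind(0, cbind(0, e, 0), 0)
  sm <- matrix(0, d[2], d[3])
  for (dr in 0:2) for (dc in 0:2)
    sm <- sm + pad[dr + seq_len(d[2]), dc + seq_len(d[3])]
  pk <- which(sm == max(sm), arr.ind = TRUE)[1, ]
  c(min(max(pk[1], 5L), d[2] - 5L), min(max(pk[2], 5L), d[3] - 5L))
}

#' Fit an LNP cell by two-stage maximum likelihood
#'
#' Stage 1 assumes an exponential nonlinearity, for which the Poisson
#' log-likelihood is concave in the filter parameters with a single global
#' maximum, and optimizes the spatial weights and temporal basis coefficients
#' by coordinate ascent (each block step is an exact Poisson GLM solve).
#' Initialization is the rank-1 factorization of the spike-triggered average,
#' its time course projected onto the raised-cosine basis. Stage 2 places 7
#' knots over the stage-1 generator-signal range, warm-starts an
#' interpolating cubic spline on the exponential curve, and alternates (i)
#' spline-coefficient maximization (the rate is linear in the knot values, so
#' this subproblem is concave) with (ii) quasi-Newton filter updates, until
#' the per-spike log-likelihood improves by less than \code{tol} or
#' \code{maxOuterIters} is reached. Temporal coefficients are renormalized to
#' unit norm after every filter step (the spatial/temporal scale split is not
#' identifiable). Block updates that fail to improve Z are rejected, so the Z
#' trajectory is non-decreasing.
#'
#' @param movie training \linkS4class{StimulusMovie} (frame duration must
#'   match the basis bin width).
#' @param raster observed \linkS4class{SpikeRaster} (>= 1 spike).
#' @param basis \linkS4class{TemporalBasis} for the temporal filter.
#' @param config a \code{\link{fitConfig}}.
#' @param rfCenter optional (row, column) receptive-field center; estimated
#'   from the spike-triggered average energy when NULL.
#' @return a \linkS4class{FitResult}
#' @export
fitLNP <- function(movie, raster, basis = raisedCosineBasis(),
                   config = fitConfig(), rfCenter = NULL) {
  d <- dim(movie@frames)
  dt <- 1 / movie@frameRate
  if (abs(dt - basis@binWidth) > 0.02 * basis@binWidth)
    stop("movie frame duration must match the basis bin width")
  nb <- ncol(basis@basis)
  nk <- nrow(basis@basis)
  cm <- frameCounts(raster, d[1], movie@frameRate)
  N <- colSums(cm)
  nSpk <- sum(N)
  if (nSpk < 1) stop("raster must contain at least one spike")
  R <- length(raster@trials)
  valid <- seq_len(d[1]) >= nb
  if (sum(valid) < 100L) stop("movie too short to fit (needs history past warm-up)")

  if (is.null(rfCenter)) rfCenter <- estimateRfCenter(movie, N, nb)
  probe <- lnpCell(matrix(1, 10, 10), rep(1, nk), rfCenter = rfCenter,
                   basis = basis)
  S <- patchMatrix(probe, movie)           # frames x 100
  B <- basis@basis
  Nv <- N[valid]

  # --- initialization -------------------------------------------------------
  if (config$init == "random") {
    a <- withSeed(config$seed, rnorm(nk))
  } else {
    Sd <- sweep(S, 2, colMeans(S))
    sta <- matrix(0, nb, 100L)             # lag x pixel
    for (lag in 0:(nb - 1L)) {
      idx <- (1 + lag):d[1]
      sta[lag + 1L, ] <- crossprod(Sd[idx - lag, , drop = FALSE], N[idx]) / nSpk
    }
    sv <- svd(sta, nu = 1, nv = 0)
    a <- qr.solve(t(B), sv$u[, 1])
  }
  a <- a / sqrt(sum(a^2))
  w <- rep(0, 100L)
  b <- log(max(nSpk / (R * sum(valid) * dt), 1e-3))

  zOf <- function(g, b) sum(Nv * (g + b)) - R * dt * sum(exp(g + b))
  zTraj <- numeric(0)

  # --- stage 1: exponential nonlinearity, coordinate ascent -----------------
  Xw <- filterColumns(S, as.vector(a %*% B))[valid, , drop = FALSE]
  zPrev <- zOf(Xw %*% w, b)
  zTraj <- c(zTraj, zPrev)
  for (it in seq_len(config$stage1MaxIters)) {
    stp <- glmBlock(Xw, Nv, R, dt)
    w <- stp$beta; b <- stp$intercept
    y <- as.vector(S %*% w)
    Xa <- vapply(seq_len(nk), function(j)
      as.numeric(stats::filter(y, B[j, ], method = "convolution", sides = 1)),
      numeric(length(y)))[valid, , drop = FALSE]
    stp <- glmBlock(Xa, Nv, R, dt)
    a <- stp$beta; b <- stp$intercept
    nrmA <- sqrt(sum(a^2))
    a <- a / nrmA; w <- w * nrmA
    Xw <- filterColumns(S, as.vector(a %*% B))[valid, , drop = FALSE]
    z <- zOf(Xw %*% w, b)
    zTraj <- c(zTraj, max(z, zPrev))
    if ((z - zPrev) / nSpk < config$tol && it > 1L) { zPrev <- max(z, zPrev); break }
    zPrev <- z
  }

  makeCell <- function(nl) lnpCell(matrix(w, 10, 10), a, nl,
                                   rfCenter = rfCenter, basis = basis,
                                   polarity = "untyped", cellId = raster@cellId)
  if (!config$useSpline) {
    cell <- makeCell(exponentialNonlinearity(gain = 1, offset = b))
    return(new("FitResult", cell = cell, zTrajectory = zTraj,
               splineStageAt = 0L, converged = TRUE, nIterations = 0L))
  }

  # --- stage 2: cubic-spline nonlinearity, alternating maximization ---------
  g <- as.vector(Xw %*% w)
  knots <- placeKnots(g, config$nKnots)
  v <- exp(knots + b)                      # warm start on the exponential curve
  floorRate <- 1e-3

  zSpline <- function(g, v) {
    lam <- pmax(splinefun(knots, v, method = "natural")(g), floorRate)
    sum(Nv * log(lam)) - R * dt * sum(lam)
  }
  cardinal <- function(g) vapply(seq_along(knots), function(k) {
    e <- numeric(length(knots)); e[k] <- 1
    splinefun(knots, e, method = "natural")(g)
  }, numeric(length(g)))

  splineStep <- function(g, v) {
    H <- cardinal(g)
    fn <- function(p) {
      raw <- as.vector(H %*% p)
      lam <- pmax(raw, floorRate)
      -(sum(Nv * log(lam)) - R * dt * sum(lam))
    }
    gr <- function(p) {
      raw <- as.vector(H %*% p)
      lam <- pmax(raw, floorRate)
      dz <- (Nv / lam - R * dt) * (raw > floorRate)
      -as.vector(crossprod(H, dz))
    }
    opt <- optim(v, fn, gr, method = "BFGS", control = list(maxit = 200))
    opt$par
  }
  filterStep <- function(X, par, v, gFixedPart = NULL) {
    # maximize Z over par with g = X par; spline nonlinearity fixed.
    sf <- splinefun(knots, v, method = "natural")
    fn <- function(p) {
      raw <- sf(as.vector(X %*% p))
      lam <- pmax(raw, floorRate)
      -(sum(Nv * log(lam)) - R * dt * sum(lam))
    }
    gr <- function(p) {
      g <- as.vector(X %*% p)
      raw <- sf(g)
      lam <- pmax(raw, floorRate)
      dz <- (Nv / lam - R * dt) * sf(g, deriv = 1) * (raw > floorRate)
      -as.vector(crossprod(X, dz))
    }
    optim(par, fn, gr, method = "BFGS", control = list(maxit = 120))$par
  }

  v <- splineStep(g, v)
  zCur <- zSpline(g, v)
  splineStageAt <- length(zTraj) + 1L
  zTraj <- c(zTraj, zCur)
  converged <- FALSE
  nIter <- 0L
  for (it in seq_len(config$maxOuterIters)) {
    nIter <- it
    zOuter <- zCur
    # (ii) filter blocks, accepted only when they improve Z
    wNew <- filterStep(Xw, w, v)
    gNew <- as.vector(Xw %*% wNew)
    zNew <- zSpline(gNew, v)
    if (zNew > zCur) { w <- wNew; g <- gNew; zCur <- zNew }
    y <- as.vector(S %*% w)
    Xa <- vapply(seq_len(nk), function(j)
      as.numeric(stats::filter(y, B[j, ], method = "convolution", sides = 1)),
      numeric(length(y)))[valid, , drop = FALSE]
    aNew <- filterStep(Xa, a, v)
    gNew <- as.vector(Xa %*% aNew)
    zNew <- zSpline(gNew, v)
    if (zNew > zCur) {
      a <- aNew
      nrmA <- sqrt(sum(a^2))
      a <- a / nrmA; w <- w * nrmA    # scale swap leaves g (and Z) unchanged
      Xw <- filterColumns(S, as.vector(a %*% B))[valid, , drop = FALSE]
      g <- as.vector(Xw %*% w)
      zCur <- zNew
    }
    # (i) spline coefficients (concave subproblem)
    vNew <- splineStep(g, v)
    zNew <- zSpline(g, vNew)
    if (zNew > zCur) { v <- vNew; zCur <- zNew }
    zTraj <- c(zTraj, zCur)
    if (zCur - zOuter < config$tol * nSpk) { converged <- TRUE; break }
  }
  cell <- makeCell(splineNonlinearity(knots, v, rateFloor = floorRate))
  new("FitResult", cell = cell, zTrajectory = zTraj,
      splineStageAt = splineStageAt, converged = converged,
      nIterations = nIter)
}
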