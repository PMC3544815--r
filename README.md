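# retinaLNP

A virtual-retina toolkit for studying neural population coding in R.

Retinal ganglion cells are commonly modeled as **linear–nonlinear–Poisson
(LNP) cascades**: the stimulus movie *s* is filtered by a spatiotemporal
linear kernel *L*, the filter output (the *generator signal*) is passed
through a static nonlinearity *N*, and the resulting rate drives an
inhomogeneous Poisson spike generator,

    λ(t) = N( (L * s)(t) ),      spikes | λ ~ Poisson(λ Δt).

`retinaLNP` implements this model and the full evaluation stack needed to ask
whether a bank of fitted model cells can stand in for real cells in
population-coding analyses:

- **Encoding** — separable LNP cells: a 10×10 spatial weight patch centered
  on the receptive field, a temporal filter spanning 1.2 s (18 bins of 67 ms)
  expressed in a 10-function raised-cosine basis, and an exponential or
  7-knot cubic-spline nonlinearity; inhomogeneous-Poisson spike sampling.
- **Fitting** — two-stage maximum likelihood on spike trains: coordinate
  ascent with an exponential nonlinearity (a concave problem with a single
  maximum), then alternation between spline-coefficient and filter updates
  until the per-spike log-likelihood converges.
- **Stimuli** — binary spatiotemporal white noise, drifting sine gratings
  (temporal/spatial frequency series), natural-like movies synthesized with
  power-law spectra (1/f^2.04 in time, 1/w^2.09 in space), and 1 s segment
  streams interleaved with 333 ms uniform gray, plus a periodogram-slope
  estimator to verify the realized spectra.
- **Information** — stimulus–response mutual information under the Poisson
  response model (Monte-Carlo, with an exact-enumeration oracle for small
  problems) and a model-free quartile estimator (response levels 0/1/2/≥3)
  with quadratic-extrapolation debiasing.
- **Decoding** — Bayesian posterior stimulus matrices from split
  train/test trials; shuffle-normalized MSE, Kullback–Leibler and
  Jensen–Shannon α indices comparing posterior matrices row by row;
  maximum-likelihood population decoding (fraction correct, conditionally
  independent cells); and a grating present/absent 2AFC task with the 75%
  contrast threshold and contrast sensitivity.
- **Ground truth** — seeded synthetic ON/OFF populations (photopic and
  scotopic presets) and `runRecovery()`, an end-to-end
  simulate → fit → evaluate harness.

## Worked example

Build a small ground-truth population, probe one cell with a
temporal-frequency grating series, and look at how much information it
carries and what its posterior stimulus matrix looks like:

```r
library(retinaLNP)

pop <- makePopulation(4, fracOn = 0.5, seed = 1)
tf  <- c(0.44, 0.75, 1.3, 2.2, 3.7, 5, 6)
ens <- makeGratingEnsemble(temporalFreqs = tf, spatialFreqs = 0.039,
                           contrast = 0.06, width = 16, height = 16)

u  <- modelRateProfiles(pop[[1]], ens, binWidth = 1/16)
mutualInformationPoisson(u, mcSamples = 20000, seed = 2)
#> MIResult: 1.309 bits (poisson_mc, dt = 0.0625 s, se 0.00993)

train <- simulateBinnedResponse(u, 25, seed = 3, sourceId = "c1")
test  <- simulateBinnedResponse(u, 25, seed = 4, trialIds = 26:50, sourceId = "c1")
round(posterior(posteriorMatrix(rateProfiles(train), test)), 2)
#>           tf00.44Hz tf00.75Hz tf01.30Hz tf02.20Hz tf03.70Hz tf05.00Hz tf06.00Hz
#> tf00.44Hz      0.36      0.24      0.08      0.01      0.07      0.09      0.14
#> tf00.75Hz      0.17      0.34      0.09      0.05      0.07      0.11      0.17
#> tf01.30Hz      0.03      0.11      0.57      0.06      0.04      0.06      0.13
#> tf02.20Hz      0.00      0.01      0.02      0.80      0.04      0.05      0.09
#> tf03.70Hz      0.04      0.09      0.03      0.08      0.58      0.06      0.11
#> tf05.00Hz      0.08      0.09      0.07      0.11      0.10      0.37      0.18
#> tf06.00Hz      0.08      0.21      0.12      0.03      0.13      0.11      0.33
```

The cell carries 1.3 of the available log2(7) = 2.8 bits at 62.5 ms
resolution; the posterior matrix shows it identifies mid frequencies
(rows 3–5 are sharply peaked on the diagonal) but confuses the lowest and
highest ones. Decoding the whole 4-cell population (cells conditionally
independent) lifts performance well above the 1/7 chance floor:

```r
profs <- lapply(pop, modelRateProfiles, ensemble = ens, binWidth = 1/16)
resp  <- lapply(seq_along(pop), function(i)
  simulateBinnedResponse(profs[[i]], 50, seed = 10 + i, sourceId = paste0("cell", i)))
fractionCorrect(profs, resp)
#> DecodeReport: overall fraction correct 0.92 (4 cells, 7 options, chance 0.143, tie rate 0)
```

A full parameter-recovery study — simulate a population, refit every cell
from its spikes alone, and check filters, held-out rates, information and
posterior α distances — is one call:

```r
runRecovery(seed = 1)
#> RecoveryReport: 5 cells (seed 1)
#>   median filter correlation:   0.991
#>   median held-out rate corr.:  0.994
#>   MI fitted/true (median):     0.998
#>   alpha medians: MSE 0.003, KL 0.028 bits, JS 0.022 bits
```

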