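---
title: "A virtual retina: LNP encoding, information, and Bayesian decoding"
author: "retinaLNP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual retina: LNP encoding, information, and Bayesian decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retinaLNP)
```

## The model

A retinal ganglion cell is represented as a linear–nonlinear–Poisson
cascade. The firing rate elicited by a stimulus movie $s$ is

$$\lambda(t) = N\big((L * s)(t)\big),$$

where $L$ is a spatiotemporal linear filter, $*$ denotes spatiotemporal
convolution, and $N$ is a static nonlinearity. $\lambda(t)$ is the intensity
of an inhomogeneous Poisson process, so the spike count in a bin of width
$\Delta t$ is Poisson with mean $\lambda(t)\,\Delta t$.

The filter is separable: a $10\times10$ spatial weight patch centered on the
cell's receptive field, multiplied by a temporal kernel spanning 1.2 s (18
bins of 67 ms, matching a 15 Hz stimulus frame rate). The temporal kernel is
expressed as a sum of 10 raised cosines on a log-stretched time axis
(`raisedCosineBasis()`): with $\phi(t) = \log(t + \tau_0)$ and evenly spaced
peaks $c_j$ of spacing $\delta$,

$$b_j(t) = \tfrac12\Big(1 + \cos\big(\pi\,\mathrm{clip}((\phi(t) - c_j)/2\delta,\,-1,\,1)\big)\Big),$$

rescaled so each function peaks at exactly 1 on the bin grid. The half-width
of two peak spacings is the standard choice for this basis; a half-width of
one spacing leaves gaps between bumps on an 18-bin grid at useful log
stretches, making rows vanish or coincide. The stretch constant
$\tau_0$ (default 0.05 s) controls how strongly early bumps are compressed;
it is a configuration default, not a measured quantity, and is only
approximately identifiable from data.

The nonlinearity is either exponential, $N(g) = \exp(\text{gain}\cdot g +
\text{offset})$, or an interpolating natural cubic spline through 7
(knot, rate) pairs with linear extrapolation beyond the outer knots. Both
are clamped below at a rate floor (default $10^{-3}$ sp/s) so spike-train
log-likelihoods stay finite; the floor, and the linear extrapolation rule,
are numerical choices the data do not constrain.

Convolution needs 1.2 s of stimulus history, so the first 17 frame bins of
any movie are marked invalid (`NA`) rather than zero-padded; they are
excluded from likelihoods, information sums, and sampled rasters.

## Fitting

`fitLNP()` maximizes the discretized Poisson log-likelihood

$$Z = \sum_{\text{bins}} \big[\, n \log \lambda - \lambda\, \Delta t \,\big]$$

(in nats, omitting the parameter-independent $\log n!$ terms) in two stages.

**Stage 1** assumes $N$ exponential, for which $Z$ is concave in the filter
parameters and has a single global maximum — two random restarts reach the
same optimum, which the test suite checks. Spatial weights are initialized
from the rank-1 SVD of the spike-triggered average (STA), the temporal
course projected onto the basis; each coordinate-ascent block step (spatial
block, temporal block, plus intercept) is an exact Poisson GLM solve
(`stats::glm.fit`). The receptive-field center, when not supplied, is the
peak of a ridge-whitened STA energy map: whitening matters because under
spatially correlated (natural) stimuli the raw STA of a balanced
center–surround filter smears into the stimulus covariance and can
mislocalize the field; a 3×3 smoothing of the energy map suppresses isolated
noise peaks.

**Stage 2** places 7 knots evenly over the realized range of the stage-1
generator signal, warm-starts the spline on the exponential curve, and
alternates (i) spline-coefficient maximization — the rate is linear in the
knot values, so this subproblem is again concave — with (ii) BFGS updates of
the spatial and temporal blocks, until the improvement per spike falls below
`tol` (default $10^{-6}$ nats/spike) or `maxOuterIters` (50) is reached.
Block updates are accepted only when they improve $Z$, so the trajectory is
non-decreasing within each stage. The spatial/temporal scale split is not
identifiable (scaling one and dividing the other leaves $Z$ unchanged), so
temporal coefficients are renormalized to unit norm after every filter step.

One honest subtlety: when the generating cell's nonlinearity is *exactly*
exponential, the 7-knot rate-spline family does not contain the exponential
optimum, and the model-family swap can lower $Z$ once, by well under
$10^{-3}$ nats/spike in our simulations. `FitResult` records the swap index
(`splineStageAt`), and the monotone-ascent invariant is enforced per stage.

## Stimuli

All generators carry luminance in abstract linear units (physical
irradiances are metadata); time bins and pixels are half-open, 0-based
intervals internally, and all generators are deterministic under a seed.

- `makeBinaryWhiteNoise()` — each pixel-frame independently takes
  mean ± amplitude with probability ½, so the RMS contrast equals the
  amplitude.
- `makeDriftingGrating()` — $m(1 + c\sin 2\pi(wx - ft))$ drifting along the
  horizontal axis with phase 0 at $t=0, x=0$; spatial frequencies above the
  pixel-grid Nyquist limit are rejected by name.
- `makeNaturalMovie()` — spectral synthesis of a Gaussian field with
  separable power laws, $1/f^{2.04}$ in temporal and $1/w^{2.09}$ in radial
  spatial frequency by default (the spectra of natural time-varying
  scenes), uniform random phases, affine rescale to the target mean and RMS
  contrast, clipping at zero luminance (warned about above 1% clipped
  mass). Only the marginal spectral exponents are specified, so separable
  synthesis is the natural minimal model; it reproduces those marginals but
  not the higher-order structure (occlusions, heavy-tailed contrast,
  spatiotemporal couplings) of real footage — a caveat for interpreting any
  passing test as a statement about real scenes.
- `assembleStream()` — 1 s labeled segments interleaved with uniform gray;
  333 ms of gray at 15 Hz is 4.995 frames and is rounded to 5 frames so
  segments stay frame-aligned.
- `estimateSpectrumExponent()` — averaged periodogram along time (per pixel)
  or space (per frame, each 2-D Fourier component entering at its radial
  frequency), least-squares slope of log power against log frequency over
  the resolvable band; returns the negated slope.

Default geometry is 32×32 pixels at 2.16 deg/pixel, chosen so a 0.058
cycles/deg grating fits about four cycles across the patch; the mapping from
screen to retina is configuration, not data.

## Information estimates

Responses are binned per 1 s segment at $\Delta t \in \{250, 125, 62.5,
31.25\}$ ms, and the per-stimulus mean counts $u_{s,k}$ (Eq.-4-style rate
profiles) define the independent-Poisson conditional
$p(r\,|\,s) = \prod_k \mathrm{Pois}(n_k; u_{s,k})$.

`mutualInformationPoisson()` estimates
$I = \langle \log_2 p(r|s)/p(r) \rangle$ with $p(r)$ marginalized exactly
over the stimulus set and the outer average taken by Monte-Carlo over
$(s, r)$ draws — except that when the truncated outcome space (counts capped
at the $1-10^{-6}$ Poisson quantile) has at most $10^6$ points the sum is
enumerated exactly. The enumeration path doubles as the independent oracle
for the sampler: the suite checks agreement within 3 standard errors on 20
random small problems. Unobserved bins are floored at $10^{-9}$ counts so
logs stay finite. All information is reported in bits; internal arithmetic
is in nats.

`mutualInformationQuartile()` is the model-free cross-check: counts map to
four response levels (0, 1, 2, ≥3 spikes — at 63 ms and 31 ms bins
essentially all bins hold ≤3 spikes), level probabilities are estimated
empirically per bin, and the per-bin plug-in informations are summed. The
many estimated probabilities carry a positive small-sample bias, so the
estimator is paired by default with quadratic-extrapolation debiasing
(`debiasQuadratic()`): the information is recomputed at trial fractions 1,
½, ¼ (20 seeded subsamples per fraction), and $I(x) = I_\infty + ax + bx^2$
in the inverse sample size $x$ is extrapolated to $I_\infty$. Summing per-bin
informations treats bins as independent carriers; for deterministic codes
that are redundant across bins the sum exceeds the joint information, which
is inherent to the estimator, not a defect of the implementation.

Whether gray-separator responses should enter the information analyses is
genuinely open; the package excludes them, which also keeps segment
responses independent of stream order.

## Posterior matrices and α indices

`posteriorMatrix()` decodes each held-out trial by Bayes' rule with a
uniform prior (the most conservative choice — all discrimination must come
from the responses) and averages the posteriors over the trials of each
presented stimulus; training profiles and test trials must be disjoint,
which is enforced through trial ids. Three row-wise distances compare a
model matrix to a reference one, each summarized by its median across rows,
the α value:

- **MSE α** (`mseAlpha`) — per-row mean squared error divided by the mean
  MSE against seeded within-row permutations of the model row (default
  100). 0 means identical; 1 means no better than shuffled; values above 1
  occur and are never clipped. Rows with zero shuffle denominator
  (identical constant rows) are excluded with a message.
- **KL α** (`klAlpha`) — $D(\text{real}\,\|\,\text{model})$ in bits after
  add-half regularization at the row's trial count, $(q n + \tfrac12)/(n +
  N/2)$, reducing to plain add-half-then-renormalize when counts are
  unavailable. The divergence direction is a documented flag because the
  usual prose ("the divergence of the model row with the real row") is
  ambiguous. An unregularized mode exists for analytic references: a delta
  row against a uniform row over 30 stimuli gives exactly $\log_2 30 = 4.9$
  bits, the stimulus entropy.
- **JS α** (`jsAlpha`) — plug-in Jensen–Shannon divergence in bits
  (midpoint mixture, base 2), symmetric, bounded in [0, 1], needing no
  regularization.

For the half-data robustness check (KL α from half versus all test trials),
the regularizer's trial count is held fixed across the two computations so
that the comparison isolates data limitation in the posterior rows
themselves rather than differing regularizer strengths.

## Decoding tasks

`fractionCorrect()` implements maximum-likelihood identification:
population log-likelihoods add across cells (conditional independence), the
argmax over options decodes the trial, and ties break deterministically
toward the lowest option index with the tie rate reported. Stimulus-
independent responses converge to the 1/|options| chance floor.

`contrastSensitivity()` mirrors a two-alternative forced-choice optomotor
task: at each temporal frequency and contrast, the decoder chooses between
"grating present" and "gray absent" from simulated Poisson responses (equal
numbers of present and catch trials); the threshold is the lowest grid
contrast with ≥75% correct, the standard 2AFC criterion, and sensitivity is
its reciprocal, peak-normalized for tuning-curve display. By default only
ON-tagged cells participate, mirroring the retinal pathway that drives
optomotor tracking. Expected segment responses are computed with 1.2 s of
gray adaptation context preceding each segment, so profiles do not depend on
which segment happened to precede them in a particular stream.

## Synthetic ground truth

`makePopulation()` draws ON/OFF cells with difference-of-Gaussians spatial
patches (center s.d. 1.0–1.5 px, surround twice as wide at 55–75% strength;
ON centers positive, OFF negative — metadata only), biphasic temporal
kernels projected onto the raised-cosine basis, and exponential
nonlinearities. The "photopic" preset uses fast, strongly biphasic kernels
(time-to-peak 70–100 ms), "scotopic" slower, more sustained ones
(140–190 ms); these presets are illustrative parameter families for
self-consistency studies, not measured values, and the package can only test
decoding consistency across presets, not biological ON/OFF findings.
Filters are scaled to unit generator-signal standard deviation under a
white-noise stimulus of RMS contrast 0.16 (the contrast-to-mean ratio of the
design stimulus), with the exponential offset set for ~10 sp/s under that
stimulus.

`runRecovery()` is the end-to-end harness: simulate a population's spike
trains on 20 minutes of training stimulus (white noise and natural movie,
50/50 by duration — models intended for broad stimulus classes are trained
on mixed statistics), refit every cell from spikes alone, then score filter
correlation, held-out rate correlation, true-versus-fitted mutual
information on a 30-snippet natural ensemble, and the three α distances
between truth-decoded and fit-decoded posterior matrices (25 training and 25
test trials per stimulus). Every stage's seed derives from one master seed
via `moduleSeed()` (a stable string hash kept below $2^{31}$), making the
whole pipeline reproducible end to end.

Default problem sizes — 5 cells, 20 min of training movie on a 16×16 field,
30 evaluation snippets, 20,000 Monte-Carlo samples per information estimate
— complete the full recovery run in about two minutes on one CPU while
leaving the parameter-recovery criteria (median filter and held-out rate
correlations ≥ 0.9) comfortably met.

## Known limitations

- No spike-history or cross-cell coupling filters: cells are conditionally
  independent by construction, so correlation-dependent population effects
  are out of reach.
- The synthetic natural movies match marginal power spectra only; claims
  verified on them do not automatically transfer to real footage.
- The quartile estimator sums per-bin informations (no joint response
  coding across bins), and the Poisson estimator inherits the independent-
  Poisson response assumption — exact for the package's own generative
  model, an approximation for anything else.
- Spline fitting is unconstrained apart from the rate floor; no
  monotonicity is imposed on the nonlinearity.
- Serialization uses JSON/CSV text formats; there is no NWB/Neo ingestion.
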