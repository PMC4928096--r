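---
title: "Point-process modeling of heartbeat dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-process modeling of heartbeat dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(heartpp)
```

This vignette documents the model, the estimators, the numerical
choices, and the deliberate design decisions of `heartpp`, at the level
of detail a user needs to interpret its outputs and a maintainer needs
to modify it.

## The probabilistic model

Heartbeats are modeled as a point process in continuous time. At any
time $t$, the elapsed time until the next R-wave event is
inverse-Gaussian with mean $\mu_{RR}(t)$ and shape $\xi_0(t)$; the
inverse-Gaussian arises as the first-passage time of an integrate-and-
fire process, which is both physiologically natural for a pacemaker and
empirically well supported by time-rescaling diagnostics. Its mean and
variance are $\mu$ and $\mu^3/\xi_0$, and the heart-rate moments used
in the estimator set are the closed-form moments of the reciprocal
variate: $E[1/W] = 1/\mu + 1/\xi_0$,
$\mathrm{Var}[1/W] = 1/(\mu\xi_0) + 2/\xi_0^2$ (verified in the test
suite against $10^6$-draw Monte Carlo).

The conditional mean is a polynomial — up to cubic — in the outputs
$l_i(t)$ of discrete orthonormal Laguerre filters applied to the
*differenced* interval series, reconstructed to seconds by adding the
most recent complete interval:

$$\mu_{RR}(t) = RR_{\tilde N(t)} + g_0 + \sum_i g_1(i) l_i +
  \sum_{i,j} g_2(i,j) l_i l_j + \sum_{i,j,k} g_3(i,j,k) l_i l_j l_k.$$

Differencing improves local stationarity; the Laguerre expansion
compresses long memory into a few coefficients. Quadratic terms carry
the spectral/bispectral analysis; cubic terms are fitted separately
(by fast orthogonal search) only for the Lyapunov path. This split
follows the principle that each downstream estimator uses the lowest
model order that defines it.

### A structural caveat: the unit root

Because the autoregression acts on differences while the mean is
reconstructed by adding the last interval, the characteristic
polynomial of the implied interval-level dynamics always contains the
factor $(z - 1)$: *every* constant-parameter NARL process of this form
is an integrated (martingale-like) process in the interval length. This
is harmless for tracking — the 90-s local window sees a locally
stationary series — but it matters for simulation: a long
constant-parameter forward run drifts without bound. The package
therefore distinguishes two generators:

* `simulate_ig_narl()` — the exact forward model, used with large shape
  (weak noise) or for short/step-change experiments;
* `simulate_ig_timeline()` / `simulate_ig_renewal()` — the renewal
  member of the family (independent inverse-Gaussian intervals with a
  time-varying mean and shape), used for long stationary recordings,
  recovery and coverage studies, and as the carrier of protocol
  effects.

## Fitting

The parameters maximize a local log-likelihood over the sliding window
$(t - W, t]$ with $W = 90$ s: the sum of log densities of the intervals
that end in the window, each weighted by $e^{-\varpi\,(t - u_j)}$ with
$\varpi = 0.02\,\mathrm{s^{-1}}$ (e-folding 50 s, chosen to keep the
effective sample inside $W$), plus a right-censoring term
$\log S(t - u_{N(t)})$ for the interval still open at $t$ (toggleable;
on by default). The defaults are $P_1 = 3$ Laguerre functions in the
linear kernel, $P_2 = 2$ in the quadratic, $\alpha = 0.2$, and a
truncation chosen as the smallest lag with $\alpha^{n/2} < 10^{-8}$
(23 lags at the default $\alpha$), at which the basis is orthonormal to
$10^{-6}$.

Numerics: the likelihood is concave-ish but not globally concave, so
the Newton–Raphson update uses analytic gradient and Hessian for the
interval terms (the censoring term's derivatives are obtained by
central differences), damped step halving until the log-likelihood is
non-decreasing, a gradient fallback when the Hessian is not negative
definite, at most 20 iterations per grid time, and a relative parameter
tolerance of $10^{-6}$. The shape is optimized as $\log \xi_0$ to
enforce positivity. Each grid time warm-starts from the previous one;
non-converged grid times carry the last estimate forward, flagged, with
a warning when more than 20% of the grid fails.

Tracking starts as soon as 20 post-burn-in intervals exist, with the
likelihood running on the partial window until a full $W$ of data has
accumulated. This choice (rather than waiting $W$) exists so that all
estimators become defined *inside* the initial 2-minute rest of the
stimulation protocol, which the feature baseline requires. Burn-in
itself (truncation + 1 intervals) is never padded: Laguerre regressors
are undefined before it, by design, because zero-padding biases the
early kernels.

The grid step defaults to 5 ms; all package examples and tests use
50–500 ms grids, which change nothing but the resolution (tests never
assume a particular step).

## Goodness-of-fit

By the time-rescaling theorem, integrating the conditional hazard over
each interval yields unit-exponential variates when the model is
correct; $1 - e^{-\Lambda_j}$ is then uniform. The hazard integral is
computed segment-wise across grid times with the identity
$\int_a^b f/S = \log S(a) - \log S(b)$ at frozen parameters. Reported:
the KS distance against the uniform with its 95% band
$1.36/\sqrt{n}$, the KS plot pairs, and the autocorrelation (lags
1–60) of the normal-inverse-transformed variates with
$\pm 1.96/\sqrt{n}$ bands. On 100 seeded 10-minute simulations from the
model itself the KS test passes in ≥ 93 runs and ~95% of ACF lags sit
inside the band — nominal coverage, recomputed in the acceptance
script.

## Spectral and bispectral estimators

The fitted autoregressive kernels live on the beat axis. They are
turned into input-output Volterra transfer functions by
$H_1(f) = 1/(1 - \Gamma_1(f))$ and
$H_2(f_1, f_2) = H_1(f_1 + f_2)\,\Gamma_2(f_1, f_2)\,H_1(f_1)\,H_1(f_2)$,
where $\Gamma_1, \Gamma_2$ are Fourier transforms of the Laguerre-
reconstructed kernels with the model's lag-1 convention. Beat
frequencies map to Hz by $f_{Hz} = f_{beat}/\mu_{RR}(t)$, per grid
time. Orders above two are rejected: the bispectrum only needs the
quadratic kernel.

The spectrum is pinned by a Parseval-type convention: the one-sided
density is $S(f,t) = 2\,\mu_{RR}\,\sigma_{RR}^2\,|H_1|^2$ so that for
the null (flat) model its integral over $[0, 0.5/\mu_{RR}]$ Hz equals
the fitted interval variance. Band powers integrate trapezoidally over
VLF 0.01–0.05, LF 0.05–0.15, HF 0.15–0.5 Hz (closed left, open
right); the LF/HF ratio floors its denominator at $10^{-12}$. Two
consequences used as oracles: the null model's LF/HF equals the
bandwidth ratio $0.10/0.35$ exactly, and a single-Laguerre model with
$\alpha \to 0$ is algebraically an AR(1), whose closed-form spectrum
the package matches to machine precision.

The bispectrum of the quadratic system driven by Gaussian innovations
of variance $\sigma_{RR}^2(t)$ is the sum over the three canonical
pairings,
$$\mathrm{Bis}(f_1,f_2) = 2\sigma^4\big[
  H_1(f_1)H_1(f_2)\overline{H_2(f_1,f_2)} +
  H_1(f_2)\overline{H_1(f_1{+}f_2)}H_2(-f_2, f_1{+}f_2) +
  H_1(f_1)\overline{H_1(f_1{+}f_2)}H_2(-f_1, f_1{+}f_2)\big],$$
evaluated on the LF ∪ HF square and integrated as $|\mathrm{Bis}|$ over
LF×LF (LL), LF×HF (LH), HF×HF (HH). It vanishes identically when
$g_2 = 0$ (a linear Gaussian process has zero bispectrum), is symmetric
in its arguments, and the vectorized surface agrees with a scalar
brute-force evaluation to $10^{-10}$ — all asserted in the tests.

## Complexity estimators

**Lyapunov exponents.** On a trailing window, a sparse cubic NAR model
is selected by fast orthogonal search: candidates are all Laguerre
monomials up to order three plus a constant; terms enter greedily by
orthogonalized residual-variance reduction until the marginal relative
reduction drops below a threshold ($10^{-4}$ default; raise it on
noise-dominated windows). The fitted map's Jacobians along the observed
states — companion form over the raw lags, first row given by the chain
rule through the Laguerre basis — are accumulated by repeated QR
factorization; exponent $i$ is the mean log of the $i$-th diagonal of
$R$, returned in decreasing order, per beat and per second. Oracles:
the logistic map at $r = 4$ gives $\ln 2$ per iteration, a linear AR(1)
gives $\log|a|$ exactly, and the QR path equals an explicitly
re-orthonormalized Jacobian product to $10^{-8}$.

**Entropy.** Approximate and sample entropy are computed in the
model's *predictive* phase space: each beat carries its predictive
inverse-Gaussian, templates are $m = 2$ consecutive pdfs, and the
distance between templates is the maximum Kolmogorov–Smirnov distance
between paired pdfs. Because both densities share the $w^{-3/2}$
prefactor, the log density ratio is a *quadratic* in $w$, so the
density crossings — the critical points of $F_1 - F_2$ — have closed
form and the KS distance is computed exactly rather than by line
search (validated against a $10^6$-point grid).

The tolerance radius realizes the conventional "0.2 × SD" ball of the
entropy literature inside the KS metric: for two inverse-Gaussians of
common scale whose means differ by $\delta$,
$\mathrm{KS} \approx 2\Phi(\delta/2\sigma) - 1$, so the ball
$\delta \le 0.2\,\sigma_{RR}(t)$ maps to the constant KS radius
$2\Phi(0.1) - 1 \approx 0.0797$ — the metric supplies the scale
normalization that the seconds-valued radius would otherwise lack.
Both orders are counted over the common template set with a common
denominator, which makes $A_I \ge 0$ by construction; sample entropy
excludes self-matches and flags a window with no order-$m$ matches as
missing rather than infinite.

The complexity estimators default to a 45-s trailing window inside
`instantaneous_estimates()` (shorter than the 90-s likelihood window)
so that they are defined early enough in the recording for the rest
baseline; both accept the full-$W$ window if set explicitly.

## Features and classification

For each stimulus, each of the 13 estimators is restricted to the last
second of the stimulus window, divided pointwise by its baseline — the
median over the first 10 s of the *covered* portion of the initial
rest (coverage begins after burn-in, so the anchor is the first rest
instant at which all 13 estimators are finite) — and summarized by
maximum, median, and median absolute deviation (MAD, unscaled):
13 × 3 = 39 dimensions. Outlier rows with any conventional z-score
above 4 are removed (zero-variance dimensions skipped); paired
condition contrasts use the exact signed-rank test below $n = 25$
(cross-checked in the tests against full sign enumeration).

Classification is a leave-one-out nu-SVM (`nu = 0.5`, radial basis,
$\gamma = 1/39$); within each fold the training split is normalized by
median/MAD (floored at $10^{-12}$ with a warning) and the held-out
sample mapped with the training constants only. Feature ranking is a
nonlinear SVM-RFE: features are eliminated by the smallest change of
the kernel-space weight criterion
$W^2 = \sum \alpha_i \alpha_j y_i y_j K(x_i, x_j)$ (cheap for RBF
kernels, where removing a feature multiplies $K$ elementwise), with
features correlated above 0.95 in the fold grouped and scored by their
average criterion (correlation-bias reduction), ties broken by original
index. Force and velocity run as two independent binary problems.

## The synthetic protocol

`simulate_protocol()` emulates the study design: 2-minute rests at both
ends, each of the four force (2, 6 N) × velocity (9.4, 65 mm/s) types
administered in randomized order with 35-s pre/post gaps, and
velocity-tied durations of 25 s (slow) and 4.3 s (fast), inside the
4.3–25 s administered range. Condition effects are injected only
inside stimulus windows as shifts of the mean interval and rescalings
of the shape; the default sizes (−70 ms and shape × 2.5 at fast
velocity; +50 ms and shape × 0.55 at slow; ±12 ms and × 1.2 with
force) were chosen once so that the velocity classes are separable but
not trivially so, and are explicitly *synthetic calibration choices*,
not estimates of physiological effect sizes. What the generator does
not emulate: respiratory sinus arrhythmia and other oscillatory LF/HF
structure (intervals are conditionally independent given the
timeline), ectopic beats, measurement jitter from finite ECG sampling,
and inter-subject variability beyond the seed. Passing tests therefore
demonstrate the correctness and stability of the estimators and the
chain on model-consistent data — not the physiological claims, which
require real recordings.

## Problem sizes and tolerances used in the checks

The test suite and acceptance script use 5–10-minute recordings on
50–500 ms grids, 100-replicate coverage runs, 200-beat entropy oracle
segments, 2000-iteration Lyapunov chains, and a 4-subject × 2-rep
protocol for the end-to-end run — sizes at which every stated tolerance
(5% mean recovery, 15% SD recovery, 0.1% spectral oracle error, 10%
Lyapunov error, $10^{-10}$ brute-force equivalences) is met with wide
margin on one CPU.

## Known limitations

* The interval-level unit root of the differenced-series NARL form
  (above): long constant-parameter forward simulations drift, so the
  renewal family is the reference generator for stationary studies.
* Artifact correction is a predictive-density tail rule (default
  $10^{-4}$ per side, merge/insert policy) — a transparent, testable
  stand-in, not a replication of any specific published real-time
  corrector.
* Kernel transforms stop at order two; the printed model-order
  notation ("p, M1, M2") in the source literature is ambiguous, so the
  orders are plain configuration (`P1`, `P2`) rather than a guessed
  mapping.
* LOO classification on very small stimulus tables (≤ 10 samples) can
  show the usual anti-learning pathology; the pipeline is meaningful
  from a few dozen stimuli upward.
* Lyapunov exponents are returned sorted, so λ₁ ≥ λ₂ holds by
  construction; only the first two are exposed as tested surface.
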