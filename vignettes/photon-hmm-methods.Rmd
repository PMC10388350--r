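---
title: "Photon-by-photon hidden Markov analysis of single-molecule FRET: models and methods"
author: "fretstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon-by-photon hidden Markov analysis of single-molecule FRET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretstates)
```

## The measurement and the model

In a diffusion-based single-molecule FRET experiment, doubly labeled
molecules drift through a confocal excitation spot and each transit yields
a *burst*: a few hundred photons spread over roughly 0.5–1 ms, each photon
tagged with its arrival time (in units of the instrument clock, here
12.5 ns) and its detection channel (donor or acceptor emission). Under
pulsed interleaved excitation (PIE), photons are also tagged with the
excitation slot, which gives a per-burst stoichiometry that separates
doubly labeled molecules from donor-only and acceptor-only species.

`fretstates` models the conformational dynamics behind these photons as a
continuous-time Markov chain over K microstates. Each microstate i has a
FRET efficiency E_i: while the molecule occupies it, a detected
donor-excitation photon is acceptor-colored with probability E_i. The chain
is equivalently described per clock tick by the stochastic matrix
T = expm(Q·Δ), with Q the rate matrix in s⁻¹ and Δ the clock period. The
central computation is the likelihood of a photon record under (Q, E, p0):
emissions apply at photon arrivals, and propagation between photons n and
n+1 multiplies by T^(δt) for the integer tick gap δt. The motivating system
is a GroEL subunit, where four microstates with shared efficiencies
(0.850, 0.608, 0.419, 0.213) interconvert on the submillisecond timescale,
and each solution condition (apo, ATP, ADP, ATP + GroES) corresponds to a
distinct *macrostate*: a fingerprint of stationary populations and exchange
rates over the same microstates.

## Likelihood machinery

The forward–backward and Viterbi recursions (in C++) handle the irregular
time base through one eigendecomposition T = U·diag(λ)·U⁻¹ per model:
propagation over a gap costs O(K²) per photon, and the Baum–Welch expected
transition counts over the unobserved ticks inside each gap use the
geometric sums S_ab(δt) = (λ_a^δt − λ_b^δt)/(λ_a − λ_b) (limit δt·λ^(δt−1)
for coincident eigenvalues), accumulated in the eigenbasis and rotated back
once per iteration. Scaled recursions keep bursts of 10⁴ photons or more
away from underflow. If the eigendecomposition fails to reconstruct T to
1e−9 (a non-diagonalizable or severely ill-conditioned matrix, which does
not occur for the models in this package's analyses), propagation falls
back to binary exponentiation of the matrix power and the gap sums to
stepwise accumulation.

Expectation–maximization updates the per-tick transition matrix from the
expected transition counts, the emission probabilities from the per-photon
posteriors, and the initial distribution from the posterior at the first
photon of each burst. Fitted rates are reported as Q = logm(T)/Δ with tiny
negative off-diagonal entries (below 1e−10 of scale) clamped to zero.
States are reported in decreasing order of fitted efficiency. In a global
fit the emission matrix is shared — its sufficient statistics are pooled
across datasets — while each condition keeps its own transition matrix and
initial distribution, which is how a multi-condition experiment pins down
one set of microstate efficiencies. Initial distributions stay per-dataset
(defaulting to each fitted chain's stationary vector) rather than shared,
since macrostates differ precisely in their occupancies.

### Initialization, restarts and convergence

EM converges to local optima, so fits are multistarted. Two deterministic
starts are used: efficiencies on a uniform grid spanning the 5th–95th
percentiles of the per-burst acceptor fractions, and a fixed wide grid from
0.1 to 0.9. The second exists because conditions that barely populate some
microstates (the ATP + GroES macrostate holds two states near 5%) produce
burst-E distributions concentrated away from those states; the data-driven
grid then starts all efficiencies inside the bulk and EM settles into a
basin that mis-places the sparse states, which the wide grid avoids (the
two basins differ clearly in log-likelihood). Remaining restarts jitter
efficiencies (s.d. 0.05) and log-rates (s.d. 0.3) around these bases, with
all exchange rates initialized at 1000 s⁻¹. Each restart runs a bounded
screening phase (30 iterations by default); the best log-likelihood then
continues to convergence, declared when the log-likelihood gain per photon
drops below 1e−8 (default cap 200 iterations). The EM trace is
non-decreasing by construction and asserted in the tests.

Model size is not selected automatically: `model_selection_report()` fits a
range of K and tabulates log-likelihood and BIC for inspection.

## The synthetic generator as the study conditions

All analyses in this package run on synthetic data whose generating values
are the published ones. `make_macrostate_fixture()` builds, for each
condition, the rate matrix k_ij = c·π_j (i ≠ j) with c = 3000 s⁻¹ and π the
published stationary populations. This construction has π as its exact
stationary vector, satisfies detailed balance, and relaxes on the single
timescale 1/c ≈ 333 μs — inside the experimentally reported 300–500 μs
exchange window. It is a deliberate stand-in: the experiment's individual
rate constants are not reproduced, only their stationary structure and
timescale, so rate-level quantities (e.g. individual k_ij) are compared
against the fixture, not against the publication. The published populations
are printed as rounded percentages (the apo row sums to 100.1%), so the
fixtures renormalize them to unit sum; entries the text does not print
(ATP π₁; ADP π₁ and π₄; ATP-ES π₁ and π₂) are completed from the unit-sum
constraint, splitting the remainder equally where two entries are missing.

Bursts are generated with exponential durations (mean 1 ms), Poisson
photons at 100 kHz during a transit for each excitation slot, exact
Gillespie state paths, colors drawn per photon from the current state's
efficiency, and ticks rounded to a 12.5 ns clock with coincident photons
pushed one tick apart. Background is off by default (recovery analyses)
and can be switched on per channel. What the generator deliberately does
not emulate: diffusion through a three-dimensional Gaussian excitation
profile (intensity varies during a real transit; here the rate is flat),
dye photophysics (blinking, bleaching), detector dead time and afterpulsing,
and spectral cross-talk (leakage and direct excitation default to zero, so
analyses operate in the proximity-ratio domain; the corrected-efficiency
formula is available and reduces to the identity at the default
coefficients). Passing recovery tests on this generator therefore
demonstrates correctness of the inference machinery under the model's own
assumptions, not robustness to those instrumental effects.

A transit that yields no detected photon is unobservable, so the generator
conditions each burst on at least one donor-excitation photon; burst
records index the emitted stream directly, and the burst search is
exercised separately on streams with genuine empty stretches.

## Validation analyses

*Recoloring* keeps every measured arrival time and redraws colors from the
fitted model; the FRET histogram of the recolored data should match the
measured one within counting noise (compared per bin at 3σ Poisson).

*Likelihood-weighted dwell times* take the Viterbi segmentation, weight
each segment by its posterior support (mean per-photon posterior of the
assigned state), censor segments touching burst edges, and estimate each
state's monoexponential mean as the weighted mean of uncensored dwells,
reported against the analytic mean 1/(−Q_ii). A hard decoded segmentation
only detects a dwell when its emission evidence (photons × per-photon
divergence between neighboring states' colors) exceeds the path's
transition penalty. At 100 kHz and 300–500 μs exchange among states 0.2
apart in E this threshold is not reached for most short dwells, so missed
dwells merge their neighbors and the fitted means overestimate — by tens of
percent for the four-state fixtures. The dwell consistency check therefore
runs where the estimator's assumptions hold (two well-separated states,
250 kHz, long bursts: agreement within 10–15%), and the four-state analysis
reports the overestimate as a documented limitation rather than hiding it.
A fully probabilistic dwell estimator (integrating over paths instead of
decoding one) would remove this bias; it is out of scope here.

*Segmentation histograms* group bursts whose decoded path never leaves one
state and histogram their burst-averaged efficiencies per state. Because
the single-state selection is itself a decoding decision, dim bursts are
both noisier and more likely to be misassigned; group means are compared to
the state efficiencies using bursts with at least ~60 donor-excitation
photons.

*Burst-wise correlation* counts photon pairs per burst on a logarithmic lag
grid (8 points per decade, 10 μs–10 ms), normalizes by the pair rate
expected for uncorrelated Poisson counts over each burst's span (with the
triangular finite-window factor), pools bursts, and scales the curve to 1
at the plateau. Normalizing per burst by the measured counts introduces a
lag-independent bias (the product of measured counts underestimates the
rate product when the two channels anti-correlate), which the plateau
scaling removes — provided the reference is well estimated, so the curve is
truncated to lags supported by at least ~10% of bursts and referenced to
the mean of its last three points. Exchange between states of different
efficiency makes the donor and acceptor count rates anti-correlated: the
donor–acceptor cross-correlation *dips* below 1 at short lags and recovers
on the exchange timescale (amplitude ≈ −Var(E)/(Ē(1−Ē)), about −0.09 for
the apo fixture), while the single-channel autocorrelations rise. The
two-state check fits G(τ) = 1 + A·exp(−τ/τ_c) and recovers
τ_c = 1/(k₁₂+k₂₁) within 30%.

## Populations, equilibrium constants and the thermodynamic cycle

Stationary populations come from the null left-eigenvector of the fitted
rate matrix (`steady_state()`, with an irreducibility check that names
unreachable states). Adjacent-microstate equilibrium constants are defined
as rate ratios K(i→i+1) = k(i→i+1)/k(i+1→i) — not population ratios —
because fitted matrices need not satisfy detailed balance; the population
ratio is reported alongside as a diagnostic. The two-macrostate cycle
stacks the apo (T) and ATP (R) ladders: relative vertical constants
α_i/α₁ = Π_{j<i} K_R(j→j+1)/K_T(j→j+1) close the cycle exactly by
construction, and free-energy differences use ΔΔG = −RT·ln(ratio) with
R = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹ at the default 295.15 K (~22 °C). The
package's energy-scale anchor −RT·ln(3.91) = 0.80 kcal/mol is an analytic
identity; cycle values computed from fitted fixtures reflect the fixture
construction, in which α ratios equal population ratios.

## Titration analysis

The likelihood test scores each burst between two macrostate models that
share emissions: score = L_sat/(L_apo + L_sat) with equal priors, computed
from per-burst log-likelihoods via a logistic of their difference. A 1 ms
transit spans only ~3 exchange correlation times, so per-burst
discrimination is intrinsically weak (log-likelihood ratios of order ±0.4);
single bursts classify reliably only when much longer. The titration
signal therefore lives in the *mean* score: the saturation curve takes the
mean score per concentration and rescales it linearly so the
zero-concentration point maps to 0 and the saturating point to 1. Under
the two-macrostate mixture assumption this scaled mean is an unbiased
estimator of the mixture fraction regardless of per-burst discrimination
(linearity of expectation), which is verified on labeled synthetic
mixtures at fractions 0–1. Standard errors come from a burst-level
bootstrap (1000 resamples).

The Hill equation Y(c) = Y₀ + A·cⁿ/(Kⁿ + cⁿ) is fitted by bounded
Levenberg–Marquardt weighted by inverse bootstrap variance, multistarted
over n ∈ {1, 2, 3, 4} with the half-saturation concentration interpolated
from the data as the K start. The baseline and amplitude stay free: the
calibrated endpoints make Y₀ ≈ 0 and Y₀+A ≈ 1, but the saturating
concentration is finite (Y(10 μM) ≈ 0.994 under the generating
parameters), and on synthetic replicates the free parameterization
recovers the Hill coefficient with the smallest sampling spread (s.d.
≈ 0.28 at 2,000 bursts per concentration; fixing the baseline or both
baseline and amplitude inflates it to 0.35–0.38). That spread is the
dominant uncertainty of the end-to-end titration recovery at these study
conditions.

## Problem sizes and numerical choices

The full-scale analyses (the reproduction script) use 5,000 bursts per
condition for fitting — about half a million donor-excitation photons per
condition — and 2,000 bursts per concentration for the titration; at these
sizes recovered efficiencies land within ±0.01 of the generating values
and stationary populations within ~1–2 percentage points. The test suite
runs the same pipelines at 2,000–2,500 bursts per condition, where
recovery comfortably clears the stated tolerances (±0.02 on efficiencies,
±3 points on populations), and exercises the likelihood core against
exhaustive path enumeration (K ≤ 3, ≤ 8 photons) at 1e−9.

Other numerical details, in brief: timestamps are doubles counting integer
ticks (exact to 2⁵³, needed because an hour of 80 MHz clock overflows
32-bit integers); burst tables use half-open index ranges; fitted tick
matrices are clamped to non-negative entries and renormalized after
eigenreconstruction; posterior vectors are renormalized per photon;
degenerate fitted states (efficiencies closer than 0.005) are flagged on
the fit object; zero-photon denominators flag the burst rather than
produce NaN; and every random stage derives its seed deterministically
from one root seed (`stage_seed()`), so each analysis stage is
independently reproducible.

## Known limitations

Background photons are not part of the emission model; recovery analyses
use background-free synthetic data, and a background rate comparable to
the burst rate would bias efficiencies toward the mixing proportions.
Dwell-time means from hard segmentation overestimate when exchange
approaches the photon time resolution (above). The burst search is the
community-standard sliding-rate window, not the publication's (unreported)
criteria. Corrected efficiencies use the standard leakage/direct-excitation/
detection-ratio formula with coefficients defaulting to the identity, as
the experimental coefficients are not available. Photon streams are read
and written in a columnar text dialect; no HDF5 reader is bundled.
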