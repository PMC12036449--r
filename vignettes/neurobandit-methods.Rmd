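---
title: "Methods and design decisions in neurobandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design decisions in neurobandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurobandit)
```

This vignette records the modeling assumptions, default parameters, and
numerical choices behind the package, and the reasoning for the decisions
that a formal model description leaves open.

## 1. Task environment

The environment is a three-armed restless bandit. Each arm's hidden
reward probability starts on the lattice {0.1, 0.3, 0.5, 0.7, 0.9} and,
independently per trial and arm, moves by ±0.2 with probability 0.1,
clipped to [0.1, 0.9].

**Direction at the interior vs the boundary.** When both directions stay
in bounds, the direction is a fair coin; at a boundary the single legal
direction is taken. The alternative — drawing a direction first and
discarding out-of-bounds moves — would make the realized change rate
depend on the current state (5% at the boundaries, 10% inside). Our
convention keeps the per-trial change frequency at exactly 10% everywhere,
which is what the acceptance test verifies on a 20,000-trial run.

**Walk updates on every trial.** The probabilities drift on all trials,
including those where the agent chooses a different arm; drift is a
property of the world, not of sampling.

## 2. Learning models

All learners share initial conditions `m0 = 0.5` (the uninformative value
for Bernoulli rewards) and `w0 = 1` (diffuse initial posterior variance).
These are fixed rather than fitted: they are identifiable only from the
first few trials and trade off directly against the learning-rate
parameters.

- **RW1 / RW2**: `m' = m + a (O − m)`, with RW2 splitting `a` into
  `aPos`/`aNeg` by outcome.
- **KF**: gain `k = (w + v)/(w + v + σ²)`, `m' = m + k (O − m)`,
  `w' = (1 − k)(w + v)`, with process noise `v` and observation noise
  `σ²`.
- **VKF**: same gain structure with the binary-observation noise
  parameter `ω` in place of `σ²`, plus the volatility recursion
  `v' = v + λ((Δm)² + w + w' − 2 wCov − v)` with
  `wCov = (1 − k) w`. Setting `λ = 0` recovers the KF exactly (a unit
  test asserts bitwise-identical trajectories), so the model family is
  properly nested.

**Unchosen arms.** Value means of unchosen arms are frozen, while their
posterior variances inflate by the process noise (`v` for the KF, the
arm's own volatility `v_j` for the VKF). This is the natural Bayesian
treatment — no likelihood information arrives about an unplayed arm, but
the world keeps drifting — and it is what gives relative uncertainty its
role in driving exploration of neglected arms.

**Choice rule.** Softmax over `βV·V + βU·U`, where under the relative
rule `V = m/Σm` and `U = w/Σw`. Relative inputs bound the softmax
arguments, making the inverse temperatures comparable across the session.
Likelihoods use the state *before* each trial's outcome; the per-trial
prediction error and relative value/uncertainty regressors are recorded
*after* the update, since they persist until the next selection and are
the quantities time-locked analyses correlate with post-feedback activity.
The volatility is floored at 1e-8 to keep the gain well-defined.

## 3. Generating agent and task timing

The synthetic study's generating agent is the VKF with
`λ = 0.2, v0 = 0.5, ω = 0.5, βV = 8, βU = 2`. Rationale: `λ = 0.2` adapts
the volatility within roughly ten trials of a change point without
destabilizing; `v0 = w0/2` starts moderately volatile; `ω = 0.5` matches
the scale of Bernoulli outcome variance; `βV = 8` on relative values
yields the strongly exploitative stay rates (>0.9) typical of this task,
and `βU = 2` adds a measurable uncertainty bonus without dominating.

Timing defaults: selection → feedback 0.5 s; feedback display plus
fixation 2.5 s; inter-trial interval Gaussian with mean 0.626 s and SD
0.072 s (truncated positive); 2 s of lead-in recording. These give
non-overlapping analysis windows: post-feedback [0, 2] s from feedback
onset and pre-selection [−1, 0] s from selection onset, which at the
500 Hz processing rate contain exactly 1000 and 500 samples, and the
standard epochs [−0.5, 2] s and [−1, 1] s contain 1250 and 1000 samples.

## 4. Synthetic neural ground truth, and its limits

Each channel is 1/f^α Gaussian background (α = 1) plus injected
components: trial-windowed oscillations whose amplitude is
`amp · max(0, 1 + slope·z)` for a z-scored behavioral regressor;
theta-phase/high-gamma-amplitude coupling
`a0 (1 + d cos φ_slow) cos φ_fast` with the slow component optionally
routed to a second region; and band oscillations whose slow envelopes mix
a shared and an independent component so the envelope correlation targets
`r`. Per-trial modulators may be events columns (e.g. PAC depth =
stay/switch decision); trials with undefined labels (the last trial's
decision) are skipped.

These generators are deliberately minimal: sinusoidal carriers with
cosine-tapered edges, no cross-frequency interactions beyond the injected
one, no nonstationary background, and channel-coherent injections within
a region. They are sufficient to give every analysis a known answer (and
known nulls), not to imitate real LFP in detail. Two artifacts of the
simplicity are worth knowing: the shared edge taper induces positive
envelope correlation between co-injected channels at the window edges,
and a perfectly periodic phase makes the circular-shift PAC null
degenerate — both are documented in the tests that work around them.

## 5. Numerical choices

- **Fitting**: free parameters are optimized unconstrained through a
  sigmoid link (unit-range) or exponential link (positive), with a
  Gaussian prior (mean 0, variance 6.25) in transformed space — flat over
  most of the unit interval but regularizing the tails. Nelder–Mead with
  seeded multi-starts; Laplace evidence with a diagonal finite-difference
  Hessian (adequate for ≤5 parameters; the evidence is used for model
  ranking, not absolute calibration). Exceedance probabilities use the
  variational Dirichlet scheme with a Monte-Carlo argmax over 1e5 draws.
- **Spectral**: the Morlet transform is implemented as one-sided Gaussian
  filtering in the frequency domain (equivalent to complex-wavelet
  convolution, and directly yielding the analytic signal), with
  reflection padding of 5 time-domain SDs. Gabor filters are unit-energy,
  fractional bandwidth 0.25, at the Gabor limit σT·σF = 1/(4π). All FFT
  lengths are rounded up to 2·3·5-smooth sizes: R's mixed-radix FFT
  degrades to quadratic cost at lengths with large prime factors, and the
  appended zeros lie beyond the reflection padding so the de-padded
  output is unaffected.
- **PAC permutation null**: the modulation index at every circular lag is
  obtained at once from one FFT cross-correlation; random lags of at
  least 10% of the series length form the null. A unit test verifies the
  FFT route against the direct shift-and-recompute loop.

## 6. Group statistics: `lmm` and `ols` engines

The faithful model is `lmerTest::lmer` with `(1 | patient)` and
`(1 | patient:channel)` random intercepts (singular nested fits are
downgraded, single-patient tables fall back to OLS). Refitting it at
every time-frequency pixel for thousands of permutations is not feasible
at any implementation speed, so the permutation machinery uses the `ols`
engine: within patient×channel centering absorbs the random intercepts
exactly (for balanced strata it is the fixed-effects estimator of the
same coefficients), after which all pixels are solved in one vectorized
pass. Because centering makes X'X invariant under within-stratum
permutation, each permutation costs one cross-product. A test confirms
the two engines produce near-identical t-maps on injected effects, and
the acceptance suite calibrates the cluster test's family-wise error
(≤ 0.08 over 200 null runs) with the `ols` engine that actual analyses
use.

Cluster tests threshold pixels at p < 0.05/(number of fixed effects),
form 4-connected clusters, drop clusters smaller than 320 Hz·ms
(4 Hz × 80 ms, with geometric bin widths on the log grid), score clusters
by the sum of squared t-values, and compare against the per-permutation
maximum. Amplitude time courses use Benjamini–Hochberg FDR at q = 0.001.

## 7. Problem sizes

The pipeline presets are the package's own choices: `smoke` (2 patients,
100 trials, 100 permutations, 1+1 channels) for CI-speed end-to-end runs,
`desk` (6 patients, 300 trials, 1000 permutations, 4+8 channels) for
development-scale analyses — the scale at which the acceptance properties
are tested — and `full` (14 patients, 500 trials, 5000 permutations,
6+14 channels) documenting a realistic study scale.

## 8. Open questions, resolved

- *Unchosen-arm treatment*: freeze means, inflate variances (see §2);
  the main alternative (decaying means toward 0.5) confounds forgetting
  with the choice rule.
- *Initial conditions*: fixed, not fitted (see §2).
- *Coupling aggregation*: coupling measures are computed per trial
  (per-trial envelope correlations; per-trial PAC z against each trial's
  own circular-shift null) rather than pooled within condition, so that
  trial-level regressors (decision, prediction error) can be modeled
  directly in the mixed models.
- *NA modulators*: per-trial injection modulators with undefined values
  skip the trial (PAC depth) or inject independent envelopes (envelope
  correlation target), keeping definitional NAs (last-trial decision,
  first-trial previous feedback) usable as ground-truth drivers.
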