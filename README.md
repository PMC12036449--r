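# neurobandit

Simulation and analysis of adaptive stay/switch decision-making in a
three-armed restless bandit, together with the intracranial
electrophysiology statistics used to relate model-derived learning
variables to prefrontal oscillatory activity.

## The scientific problem

In volatile environments, decision-makers must track not only how good
each option is, but how *uncertain* and how *changeable* those values are.
A volatile Kalman filter (VKF) formalizes this: each arm of the bandit
carries a value estimate, a posterior variance, and a volatility estimate
that is itself learned from the data. Choices follow a softmax over
*relative* value and *relative* uncertainty, so that uncertainty can act
as an exploration bonus. The package implements:

- **Task environment** (`banditConfig`, `simulateProbabilityWalk`,
  `simulateAgent`): three arms whose hidden reward probabilities each have
  a 10% chance per trial of stepping by ±0.2 inside [0.1, 0.9].
- **Learning models** (`sessionTrajectory`, `rwUpdate`, `kfUpdate`,
  `vkfUpdate`): Rescorla–Wagner (one or two learning rates), Kalman
  filter, and volatile Kalman filter, crossed with value-only,
  uncertainty-only, and value-plus-uncertainty softmax rules. VKF with
  λ = 0 reduces exactly to the Kalman filter.
- **Model fitting** (`mapFit`, `hierarchicalFit`,
  `exceedanceProbability`, `parameterRecovery`): MAP estimation with a
  Gaussian prior in transformed space, Laplace model evidence,
  empirical-Bayes group priors, and random-effects exceedance
  probabilities.
- **Synthetic neural ground truth** (`recordingSpec`, `generateDataset`):
  1/f-background local field potentials with injected, behavior-locked
  effects — regressor-modulated band power, theta-phase/gamma-amplitude
  coupling, and inter-regional envelope correlation — so every analysis
  can be validated against a known answer.
- **Spectral analysis** (`morletTFR`, `gaborHAA`, `epochSignal`): complex
  Morlet time-frequency maps on a 50-bin logarithmic 4–150 Hz grid, and
  band-limited analytic amplitude via a unit-energy Gabor filter bank.
- **Coupling statistics** (`pacMI`, `pacPermutationZ`, `pacGridSearch`,
  `aac`, `couplingTable`): modulation index with a circular-shift
  permutation null (computed for all lags at once via FFT
  cross-correlation), and per-trial amplitude–amplitude correlation.
- **Group statistics** (`fitLME`, `clusterPermutation2d`,
  `timecourseRegressionFDR`): mixed-effects models with patient and
  channel-in-patient random intercepts, 2D cluster-based permutation
  tests on time-frequency t-maps (320 Hz·ms area threshold), and
  FDR-corrected amplitude time courses.
- **Pipeline** (`validateConfig`, `runPipeline`): a YAML-configurable
  end-to-end run at smoke/desk/full scale writing CSV/JSON artifacts.

## Worked example

```r
library(neurobandit)

## 1. Simulate a session of the restless bandit under the generating agent
cfg <- banditConfig(nTrials = 300, seed = 42)
spec <- modelSpec("VKF", "value_and_uncertainty", useRelative = TRUE)
params <- list(lambda = 0.2, v0 = 0.5, omega = 0.5, betaV = 8, betaU = 2)
sess <- simulateAgent(cfg, spec, params, seed = 43)
sess
#> BanditSession: 300 trials, 3 arms
#>   reward rate: 0.387  stay rate: 0.936

c(winStay = winStay(sess), loseShift = loseShift(sess))
#>    winStay  loseShift
#> 0.98275862 0.09289617

## 2. Recover the latent learning trajectory
traj <- sessionTrajectory(sess, spec, params)
head(trajectoryTable(traj, sess)[, c("trial", "choice", "outcome",
                                     "m1", "m2", "m3", "k", "pe")], 4)
#>   trial choice outcome  m1        m2        m3         k          pe
#> 1     1      3       1 0.5 0.5000000 0.8750000 0.7500000  0.50000000
#> 2     2      3       0 0.5 0.5000000 0.2959831 0.6617336 -0.87500000
#> 3     3      2       1 0.5 0.9166667 0.2959831 0.8333333  0.50000000
#> 4     4      2       1 0.5 0.9755102 0.2959831 0.7061224  0.08333333

## 3. Fit the model by MAP and compare against simpler learners
fit <- mapFit(sess, spec, seed = 1)
fit
#> subjectFit: VKF / value_and_uncertainty
#>   params: lambda=0.186, v0=0.486, omega=0.526, betaV=11.5, betaU=2.69
#>   NLL = 12.46  BIC = 53.44  logEv = -18.42

sessions <- lapply(1:4, function(i)
  simulateAgent(banditConfig(nTrials = 300, seed = 100 + i), spec, params,
                seed = 200 + i))
grid <- list(modelSpec("RW1", "value_only", FALSE),
             modelSpec("KF", "value_only", TRUE),
             spec)
gf <- hierarchicalFit(sessions, grid, nStarts = 4, seed = 3, maxIter = 25)
gf
#> groupFit: 4 subjects x 3 models
#>   RW1/value_only                   xp = 0.053  sum logEv = -829.6
#>   KF/value_only/rel                xp = 0.396  sum logEv = -264.4
#>   VKF/value_and_uncertainty/rel    xp = 0.552  sum logEv = -95.3

## 4. Phase-amplitude coupling on an analytically coupled signal
fs <- 500
x <- genBackground(8 * fs, fs, alpha = 1, seed = 7)
phi <- Arg(neurobandit:::.gaussFilterBank(x, fs, 8, 2)[, 1])
amp <- 1 + 0.8 * cos(phi)
pacMI(amp, phi)
#> [1] 0.3996624
pacPermutationZ(amp, phi, nPerm = 500, seed = 8)
#> PAC: mi = 0.3997, z = 16.01 (null 0.03829 +/- 0.02257, 500 perms)
```

An end-to-end synthetic study (behavior → model comparison → neural
generation → coupling → group statistics) runs with:

```r
res <- runPipeline(list(preset = "smoke", seed = 1), outDir = "run01")
```

## Reproduction

- `tests/testthat/test-acceptance.R` encodes the acceptance criteria:
  frequency-grid geometry (18 bins below 15 Hz, 22 above 30 Hz), epoch
  sample counts (1250 post-feedback, 1000 selection-stage at 500 Hz), the
  320 Hz·ms cluster area threshold, the 10% walk change rate within a
  3-sigma binomial interval at ≥ 10,000 trials, and the statistical
  property suite (exact VKF/KF nesting, analytic modulation index 1/2,
  permutation-z null calibration, cluster-test family-wise error ≤ 0.08
  over 200 null runs, parameter recovery r > 0.7 at 300 trials × 12
  subjects, exceedance-probability symmetry/dominance, and sign recovery
  of injected coupling→decision and coupling↔prediction-error effects).
- `scripts/acceptance.R` reports the walk change frequency on a long run:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out acceptance.json
  # t6: 10.14098 % over 44759 interior (trial, arm) events
  ```

- `vignettes/neurobandit-methods.Rmd` documents the modeling assumptions,
  parameter defaults, and numerical choices.

All randomness is seeded through function arguments; rerunning any example
above reproduces its output exactly.
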