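---
title: "Methods: sleep-EEG brain age, hypoxic burden, and CPAP response"
author: "somnage package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep-EEG brain age, hypoxic burden, and CPAP response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnage)
```

# The scientific problem

Obstructive sleep apnea (OSA) fragments sleep and causes intermittent
hypoxemia; both are believed to accelerate brain aging. A sleep-EEG-derived
**brain age index (BAI)** — predicted brain age minus chronological age —
offers a physiological readout of that process, and its change between a
baseline and a follow-up polysomnogram (PSG) measures whether therapy
(continuous positive airway pressure, CPAP) slows or reverses it. This
package implements the complete analysis chain:

1. simulate or read PSG nights (EEG, airflow, SpO2, hypnogram, arousals);
2. clean the sleep EEG and convert it to a fixed-shape time-frequency
   tensor;
3. estimate brain age, BAI, and annualized BAI change
   (`annual delta-BAI = (BAI_followup - BAI_baseline) / interval`);
4. score respiratory events and compute apnea-/hypopnea-specific hypoxic
   burden and the standard per-hour indices;
5. run the longitudinal statistics (paired tests, covariate-adjusted group
   contrast, FDR-controlled association scans);
6. predict individual CPAP response from baseline features with a
   classifier battery over NCA-ranked feature sets.

Because the clinical cohorts this design targets are not public, the
package is organized around **parameter recovery on a synthetic cohort
generator**: the generator encodes the documented cohort structure
(sample sizes, age and severity distributions, group-specific annual BAI
drift of -0.6 +/- 2.7 years/year under treatment versus +0.3 +/- 2.6
untreated), and the analysis code must recover those parameters from raw
simulated signals. Everything is deterministic under a seed.

# The synthetic cohort generator

`generateCohort()` draws latent subjects. Three correlated standard-normal
latents drive each subject: a severity latent (shared by AHI, arousal
index, ODI, the apnea/hypopnea split, and hypoxic burden), a baseline
brain-age-offset latent, and an age latent. The observable severity
features are transformations of these latents calibrated to the reference
cohort tables: log-normal AHI with median 42.1/h (treated preset) or
23.4/h (untreated), arousal index 37.7/30.1 per hour, total hypoxic burden
scaling like `0.38 * AHI^1.5` (matching group means of roughly 151 and 62
percent-minutes/hour).

Annual drift is `drift_mean + drift_sd * z`, where `z` is a unit-variance
combination of the three latents plus residual noise. The preset weights
reproduce the observed *sign pattern of effect modification*: untreated
drift rises with baseline severity and baseline BAI; treated (improvement)
drift becomes more negative with severity, baseline BAI, and age. Because
the modifiers are centered, the cohort mean drift is the preset mean
regardless of the weights, so effect modification and mean recovery can be
tested independently. Setting all structural weights to zero gives pure
noise drift; setting `drift_sd = 0` makes drift exactly the mean (both are
exercised in the tests).

Per-night signals:

* **Hypnogram** (`generateHypnogram()`): a run of wake epochs (sleep
  latency, Poisson mean 18 epochs) followed by a sticky Markov chain over
  `N1, N2, N3, REM` whose stationary N1 fraction increases with AHI
  (`0.22 + 0.0017 * AHI`), emulating fragmentation. There is no wake after
  sleep onset, so TST is exact — convenient for index arithmetic. This is
  a deliberate simplification; real nights have WASO.
* **EEG** (`generateEEG()`): per-epoch colored noise built from
  log-frequency Gaussian spectral components (delta/theta/alpha/sigma/
  beta/gamma) with stage-dependent weights (N3 delta-dominant, wake
  alpha-dominant). The aging signal is a linear decline of the delta
  component's log10 power with *true brain age* (default 0.01 log10
  units/year; theta at half that), on top of a stable per-subject spectral
  trait (SD 0.02 log10 units — the irreducible noise floor for any age
  regressor, about 2 years) and per-epoch jitter (SD 0.1) that averages
  out across the night. A shared pink-noise trace feeds the mastoids and
  every scalp channel, so contralateral re-referencing has a real common
  component to remove.
* **Respiration** (`generateRespiration()`): breathing is an
  amplitude-modulated 0.25 Hz oscillation on both airflow sensors. Apneas
  suppress the envelope by 92-98 percent for 12-35 s; hypopneas suppress
  the nasal envelope by 35-75 percent for 15-40 s. Events are placed in
  sleep with at least 10 s gaps, at a rate matching the subject's AHI.
  Each desaturating event subtracts a dip that falls linearly from event
  start to a nadir 20 s after event end and recovers exponentially
  (tau = 10 s) — a shape chosen so expected hypoxic areas are analytically
  tractable in tests. Optional artifacts drop SpO2 below 60 percent.
  The planted events are returned as ground truth for detector validation.

What the generator does **not** emulate: cardiorespiratory coupling,
realistic ECG/EOG artifact waveforms, WASO and REM cycling structure,
position effects, and any nonlinearity between severity and drift beyond
the linear effect-modification weights. Passing tests therefore show that
the estimation chain is correct and well-calibrated *under the stated
generative assumptions*, not that it would achieve the same numbers on
real recordings.

# EEG preprocessing

`preprocessPSG()` applies, in a fixed order: contralateral mastoid
re-referencing (F3-A2, C3-A2, O1-A2, F4-A1, C4-A1, O2-A1), sleep-latency
trimming, zero-phase 0-50 Hz band limiting, reference-channel artifact
regression, 5-SD spike interpolation, bad-channel replacement, and
per-channel z-scoring. Choices worth recording:

* The step order puts referencing and trimming first so every statistic
  (SDs for spike flagging, z-scoring moments) is computed on the analyzed
  segment only.
* The band limit has a 0 Hz lower edge, i.e. it is a pure low-pass:
  a 101-tap linear-phase FIR (Hamming), normalized to exact unit DC gain,
  applied by FFT convolution with group-delay compensation — zero phase,
  with stop-band attenuation beyond 40 dB at 60 Hz.
* Artifact regression is a least-squares projection of each channel onto
  the span of supplied ECG/EOG reference signals. When no reference
  channels exist (the synthetic montage has none) the step is skipped and
  logged, never silently.
* Spike interpolation computes each channel's mean and SD once over the
  whole trimmed recording (single pass, no re-estimation), flags samples
  beyond 5 SD, and bridges each flagged run linearly between its nearest
  clean neighbours (nearest-value extension at the edges). The threshold
  is per channel; pooling channels was the open alternative, and
  per-channel was chosen because channel gains differ.
* A channel whose flagged fraction exceeds 30 percent is replaced by its
  opposite-hemisphere homologue (F3 with F4, C3 with C4, O1 with O2); if both
  channels of a pair exceed the threshold the recording is rejected.
* Z-scoring is per channel over the whole recording; it makes the
  downstream scalogram sensitive to spectral *shape* rather than absolute
  amplitude, which is also why the generator encodes age in relative
  spectral content.

# Scalogram and model input

`cwtPower()` computes an analytic Morlet continuous wavelet transform
(omega0 = 6) at 16 band centers, by default log-spaced from 0.5 to 48 Hz
(the ladder is configurable; no canonical list exists for this
representation). Wavelets are amplitude-normalized — unit peak frequency
response — so a pure tone yields the same power whatever its frequency,
while broadband-noise band power grows with each band's absolute
bandwidth. `binTime()` averages log10 power within 2000 equal-width time
bins (the last bin absorbs the remainder); `resampleStages()` assigns each
bin the stage of the epoch containing its center, coded on a `[0, 1]` grid
(`W=0, N1=0.25, N2=0.5, N3=0.75, REM=1`); `assembleInput()` stacks the six
channel scalograms with the stage vector broadcast across the band axis
into the fixed `2000 x 16 x 7` tensor. Broadcasting is the natural way a
`2000 x 1` stage vector becomes a seventh `2000 x 16` channel; the
concatenated shape dictates it.

# Brain-age models

The regressor is a *contract* with three kinds:

* `ridge` (default): ridge regression (`glmnet`, alpha = 0, penalty chosen
  by internal cross-validation) on 101 summary features — mean log10 power
  per band and channel (96) plus the five stage fractions. Fast and
  deterministic; the reference trainable model.
* `mlp`: a single-hidden-layer perceptron (`nnet`, 16 units by default) on
  the same features, for a nonlinear check of the contract.
* `oracle`: returns the generator's true brain age plus seeded Gaussian
  noise (default SD 0.5 years). It requires ground-truth metadata and
  exists so every downstream computation (BAI arithmetic, longitudinal
  statistics, responder labeling) can be validated independently of
  regressor quality.

No bias correction is applied to predictions (none is part of the design
this package follows). Predictions are clamped to `[0, 120]` years.
The benchmark (`brainAgeMAEBenchmark()`) trains on 160 of 200 simulated
subjects with ages uniform on 20-80 and reports held-out MAE on 40; the
package's acceptance bound is 4.8 years, and the ridge kind typically
achieves about 3 years under the default generator settings. The benchmark
simulates 10-minute nights: the spectral age signal is stationary within a
night, so night length trades Monte-Carlo noise in the per-night features
against runtime, and 10 minutes keeps the 200-subject benchmark
desk-scale. The training population deliberately has a *small* true
brain-age offset dispersion (SD 3 years): a model-development population
of reference sleepers, against which chronological age is a meaningful
training target. Training such a model on a severe-OSA cohort would
conflate the offset with noise.

# Respiratory analysis

* `cleanSpo2()`: samples below 60 percent are sensor artifact and are
  replaced by the most recent preceding valid value (leading samples take
  the first valid value). A night with more than 20 percent of samples
  below 60 is flagged unusable for hypoxic-burden computation (the burden
  becomes `NA`); the replacement is still applied. The operation is
  idempotent.
* `breathEnvelope()`: moving RMS over 4 s, then a 1-s smooth. All event
  logic uses envelope *ratios* to a running baseline, so the indices are
  invariant to the airflow units.
* `detectEvents()`: the baseline at each instant is the mean envelope over
  the preceding 100 s of non-suppressed breathing (samples below 70
  percent of baseline on either sensor are excluded from the baseline
  buffer — during a long event the baseline therefore holds its pre-event
  value). An apnea is a thermal-envelope drop to <= 10 percent of
  baseline; because a moving-RMS envelope smears the edges of a deep drop,
  the deep core (>= 4 s) marks the event and the duration criterion
  (>= 10 s) is applied to the enclosing <= 70 percent suppression span,
  which tracks the true airflow-reduction interval. A hypopnea is a
  nasal-envelope drop to <= 70 percent for >= 10 s, corroborated by a
  >= 3 percent SpO2 fall from the pre-event 100-s maximum within 45 s of
  event end, or an arousal overlapping `[start, end + 5 s)`. Contiguous
  criterion spans merge into one event; apneas take precedence over
  overlapping hypopnea candidates.
* `eventHypoxicArea()` / `hypoxicBurden()`: per event, the baseline is the
  maximum SpO2 in the 100 s before event end; the search window is
  `[start, end + 45 s)` clipped at the next event's start; the area of the
  positive deficit is integrated by the trapezoid rule on the 1-Hz grid
  and reported in percent-minutes. The exact window construction used by
  the published ensemble-averaged approach is not reproducible from the
  available description, so these two constants (100 s, 45 s) stand in
  and are configuration-exposed. Because windows always clip at the next
  event of any type, apnea-specific plus hypopnea-specific burden equals
  the total exactly, for every night.
* `computeIndices()`: counts per hour of TST (non-wake epochs times 30 s).
  ODI counts >= 3 percent desaturations below the preceding 100-s maximum
  sustained >= 5 s, merging episodes separated by < 10 s; the 3 percent
  threshold mirrors the hypopnea criterion.

# Longitudinal statistics

`pairedTTest()` is the classical paired t on follow-up minus baseline
(degenerate all-zero differences return `t = 0, p = 1`).
`adjustedGroupComparison()` regresses the outcome (delta-BAI or annual
delta-BAI) on a treated-indicator plus covariates — sex, age, BMI, AHI,
arousal index by default — and reports the group coefficient; with no
covariates it reduces exactly to the pooled two-sample t. Collinear
designs error with the offending column named. `associationScan()` fits
one univariable linear model per baseline feature and applies
Benjamini-Hochberg FDR across the scanned set. The scan is univariable
(rather than one multivariable model) because the per-feature statistics
it is designed to reproduce are of like magnitude and individually
FDR-adjusted; this was a genuinely open reading and is the package's
choice. Sex is coded 0/1 (male = 1) everywhere.

# Responder prediction

`medianSplit()` labels subjects at or below the cohort-median annual
delta-BAI as good responders (ties at the cutoff are good; a fully tied
cohort is all good — documented degenerate case). With an even number of
distinct values the split is exactly even, e.g. 49/49 at n = 98.

`ncaFeatureWeights()` implements the diagonal (feature-selection) variant
of neighborhood component analysis: distances
`d_ij = sum_k w_k^2 (x_ik - x_jk)^2`, softmax neighbor probabilities
`p_ij = exp(-d_ij) / sum_{l != i} exp(-d_il)`, objective = mean
leave-one-out same-class probability minus `lambda * sum w_k^2`
(`lambda = 1/n` by default, the conventional scaling). Gradient ascent
starts from `w = 1` with an adaptive step: accepted steps never decrease
the objective; convergence at an accepted change below `1e-6` or 500
iterations. The analytic gradient is validated against central finite
differences in the test suite. Weights are constrained non-negative.

`buildFeatureSets()` forms the eight canonical sets over the 11 baseline
features (BAI, age, sex, AI, AHI, apnea index, hypopnea index, ODI, and
total/apnea-/hypopnea-specific HB): all, top-1/3/5 by NCA rank, the EEG
pair {BAI, AI}, the non-EEG complement, all-but-BAI, and BAI alone.

`evaluateGrid()` runs KNN, a 16-unit single-hidden-layer perceptron, a
decision tree, a random forest, and an SVM with cubic polynomial kernel
over the eight sets under stratified 5-fold cross-validation.
Standardization and the NCA ranking are refitted inside each training fold
by default — the ranking is a supervised step, and refitting avoids
selection leakage — while `paperFaithful = TRUE` reproduces the simpler
design of a single ranking on all data. Metrics (accuracy, rank-statistic
AUC, sensitivity and specificity with good responder as the positive
class) are computed on pooled out-of-fold predictions by default; per-fold
metrics are attached as an attribute. Classifier hyperparameters beyond
the SVM kernel are package defaults, documented in `?evaluateGrid`.

# Numerical and degenerate-input policy

Zero-variance channels error at z-scoring and are rejected before NCA;
features constant within a CV training fold are excluded from that fold's
ranking and appended last. SpO2 values outside `[0, 100]` are rejected at
container validation. An all-wake hypnogram has no sleep onset and errors.
Event lists validate the 10-s minimum duration, ordering, and within-type
non-overlap. All interval annotations are half-open `[start, end)` seconds
from recording start. Seeds derive hierarchically from one master seed via
a fixed integer recurrence, so every artifact is reproducible bit-for-bit
and all derived seeds stay below 2^31.

# Problem sizes

The test-suite and benchmark problem sizes are the package's choices for a
single-CPU desk run: 20-replicate recovery of the cohort drift means at
the reference sample sizes (98 treated, 88 untreated); a 200-subject
model-development cohort with 10-minute nights for the regressor MAE
benchmark; 1,000 fuzz cases for the hypoxic-area integrator; 300-subject
cohorts for association-scan sign recovery; and a 12 + 10 subject
end-to-end smoke run with 6-minute nights. Each was chosen to make the
statistical assertion it supports comfortably stable under its fixed seed.

# Known limitations

* The trainable regressors are linear/shallow models on band-power
  summaries, not the convolutional architecture the tensor shape was
  designed for; the contract isolates downstream analyses from this
  choice, and the tensor is the faithful input shape for a future
  convolutional kind.
* Detector duration measurement depends on envelope smoothing constants;
  very short events (close to 10 s) near the criterion boundary are
  sensitive to them.
* The generator's severity-drift couplings are order-of-magnitude choices
  matching a reported sign pattern and t-statistic scale, not fitted to
  any data; recovery results quantify estimator correctness, not clinical
  effect sizes.
* Hypnograms lack WASO and REM cycling; stage-dependent analyses beyond
  stage fractions would need a richer stage model.
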