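---
title: "Ear-EEG endogenous BCI analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ear-EEG endogenous BCI analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earbci)
```

## The problem

Electrodes placed behind the ears (ear-EEG) are far less obtrusive than a
full scalp montage, which makes them attractive for brain-computer
interfaces (BCIs) that people might actually wear. Most ear-EEG BCIs to
date have been *exogenous*: they decode responses evoked by external
stimuli, which requires stimulus hardware and fatigues the user. An
*endogenous* BCI instead decodes self-generated mental activity — here,
mental arithmetic (MA, serial subtraction) versus a light cognitive task
(LC, imagined recitation of the alphabet), a binary code that needs no
stimulus at all.

The scientific questions this package operationalizes are:

1. Do ear electrodes pick up enough of the classical eyes-closed alpha
   increase to be useful? This is quantified per region of interest (ROI)
   as `SNR = 10 log10(alpha power EC / alpha power EO)` in decibels.
2. Do the task-related spectral signatures — alpha event-related
   synchronization (ERS) and a broad beta/gamma event-related
   desynchronization (ERD) during MA — appear behind the ear as they do on
   the scalp?
3. Can MA be discriminated from LC from six behind-the-ear channels at the
   ~70% accuracy conventionally considered the floor for binary
   communication?

The montage is 31 channels: 25 scalp electrodes in 10-20 positions plus
R1-R3/L1-L3 behind the ears, grouped into four six-channel ROIs (frontal,
central, occipital, ear). Scalp ROIs are re-referenced with a six-channel
common average (CAR); the ear ROI uses an opposite-ear reference (each
side referenced to the mean of the other side's three electrodes). A fifth
pseudo-ROI `"scalp"` (25-channel CAR) serves as the all-electrodes
reference condition.

## The processing chain

For each subject the chain is:

1. zero-phase 4th-order Butterworth bandpass 1-50 Hz (`bandpass()`),
2. decimation to 200 Hz (`downsample()`),
3. per-ROI re-referencing (`rereference_car()`, `rereference_ear()`),
4. epoching -2 to 10 s around each task onset (`extract_epochs()`),
5. baseline correction over -2 to 0 s (`baseline_correct()`),
6. peak-to-peak artifact rejection (`reject_peak_to_peak()`; defaults
   126.67 uV for task trials, 196 uV for resting blocks — mean values of
   the subject-specific thresholds used in practice),
7. analysis: STFT alpha SNR (`ec_eo_snr()`), ERD/ERS maps
   (`erders_map()`), and per-ROI classification (`cross_validate()`:
   multi-band CSP + shrinkage LDA under 10x10-fold stratified CV),
8. group statistics across ROIs (`friedman_test()`,
   `pairwise_wilcoxon()`, `bonferroni()`).

`run_ec_eo_study()` and `run_ma_lc_study()` orchestrate the two studies
over a set of simulated subjects with per-subject seeds and a JSON
manifest sufficient to reproduce every output byte.

## The synthetic-data generator

No public recordings accompany the experimental design this package
implements, so the generator in `simulate_recording()` is a first-class
module: it produces continuous 31-channel EEG whose *statistical
structure* matches what the analysis assumes, with known ground truth, so
every downstream stage can be validated end to end.

The signal model is a sum of spatially mixed sources plus per-channel
`1/f` noise:

* **Alpha sources.** Amplitude-modulated ~10 Hz sinusoids with a slow
  (+/- 0.5 Hz) frequency random walk, sited under the six occipital ROI
  electrodes (relative amplitude 1) with satellites at C3/C4 (1.10) and
  F3/F4 (0.65) — alpha is posterior-dominant but present over the whole
  scalp. The eyes-closed gain applies fully to the posterior sources and
  with amplitude exponent 1/2 to the satellites: the eyes-closed rise is
  the posterior (Berger) rhythm, whereas task-related alpha modulation is
  widespread; this separation is what lets a small frontal EC/EO SNR
  coexist with a clearly visible frontal task ERS, as observed in real
  recordings. Each source has an independent lognormal envelope
  (`envelope_sd`, default 0.45 log-units, ~2 s correlation time)
  normalized to unit mean square, so condition gains change *mean* power
  without changing the envelope statistics.
* **Beta/gamma background.** Band-limited (14-50 Hz) noise sources under
  all 18 frontal/central/occipital ROI electrode sites, with the same
  envelope model.
* **Mixing.** Source-to-channel weight `exp(-d / mixing_spread)` with
  `d` the 2-D head-schematic distance and `mixing_spread = 0.4` head
  radii. This is deliberately not a biophysical forward model: the only
  property the analysis needs is the leakage ordering
  occipital >> ear > central > frontal after per-ROI re-referencing,
  which the exponential decay delivers robustly. The ear electrodes sit
  posterior-inferior (near the mastoid), which is what makes them
  privileged receivers of occipital alpha.
* **Noise.** Independent per-channel `1/f^noise_exponent` noise
  (`noise_scale` = 5 uV RMS), generated by a cascade of log-spaced
  first-order pole-zero sections (accurate to a few percent of slope
  across 0.1-450 Hz, and far cheaper than FFT shaping at awkward
  lengths).
* **Blinks.** `inject_blinks()` adds ~300 ms frontal-dominant bumps
  (maximal at Fp1/Fp2, amplitude 300 uV) at Poisson times and records the
  ground-truth onsets. The default 0.5 events/min models a subject who
  suppresses blinks during trials, so that roughly 5-10% of 12 s epochs
  are contaminated — the rejection counts this produces match what is
  typically reported for this paradigm (~4 of 50 trials).

Condition effects are multiplicative amplitude envelopes with 0.5 s
raised-cosine ramps at event edges:

| parameter          | default | meaning                                        |
|--------------------|---------|------------------------------------------------|
| `ec_alpha_gain`    | 2.0     | alpha amplitude while eyes are closed          |
| `ma_alpha_ers`     | 1.8     | alpha amplitude during MA (power x 3.24 = ERS) |
| `ma_beta_gamma_erd`| 0.7     | beta/gamma *power* factor during MA (ERD)      |
| `lc_alpha_gain`    | 1.15    | mild alpha amplitude gain during LC            |

The absolute source amplitudes were fixed once, analytically, from the
post-reference leakage geometry so that the four ROI EC/EO SNRs land near
the magnitudes reported for real recordings of this paradigm
(~0.7 / 1.5 / 4 / 2.5 dB for frontal / central / occipital / ear) and the
per-ROI decoding accuracies land in the 80-95% range, comfortably above
the 70% binary-communication floor, with occipital highest. These effect
sizes are configuration, not claims: the generator defines the study
conditions under which the pipeline is exercised.

`roi_alpha_gain` multiplies the alpha leakage into a ROI's channels on
top of the distance decay (all 1 by default); it exists to let users
distort the spatial pattern without touching the geometry.

**What the generator does not emulate.** Volume conduction through a
realistic head, EMG/ECG artifacts, electrode drift and popping,
inter-subject anatomical variability, session effects, and non-stationary
task engagement. Passing tests on synthetic data therefore demonstrate
that the *pipeline* is correct and well calibrated — that injected
effects of the assumed form are recovered, orderings are reproduced, and
no information leaks across cross-validation folds — not that real
recordings would yield the same numbers.

## Classification details

Per ROI and frequency band (delta 1-3, theta 4-7, alpha 8-13, beta 14-29,
gamma 30-50 Hz), trials are zero-phase bandpassed and their task-window
(0-10 s) channel covariances computed. Class covariances are trace
normalized per trial and averaged; CSP solves
`C1 w = lambda (C1 + C2) w` via whitening of the composite covariance.
Two design points deserve a note:

* **Rank truncation.** A CAR-referenced six-channel group is rank 5; the
  whitening is restricted to the numerical rank of the composite
  (relative eigenvalue tolerance 1e-9) on top of a 1e-8 ridge. Without
  this, one "spatial filter" points into the null space and its
  log-variance is numerical noise, which poisons the shrinkage estimate
  of the feature covariance (the shrinkage target `nu I` inherits an
  absurd scale and the discriminant collapses).
* **Component selection.** "First and last" components per band is read
  as 2 + 2 (4 filters, 20 features over 5 bands); `n_keep = 1` is
  available where the tighter reading is wanted.

Features are natural-log variances of the filtered, projected task
window. The classifier is LDA with the pooled covariance shrunk as
`(1 - gamma) S + gamma nu I`, `nu` the average eigenvalue and `gamma` the
analytic Ledoit-Wolf intensity computed from the pooled class-centred
training features. A zero decision score is assigned to MA (a fixed,
arbitrary tie-break). Evaluation is 10-fold stratified CV repeated 10
times; CSP and LDA are refitted inside every training fold, so no
information from held-out trials reaches the models — the null-effect
calibration test verifies that this keeps chance-level data at 50%.

## Numerical choices

* "Zero-phase 4th-order Butterworth" is implemented as a design-order-4
  filter run forward and backward (zero net phase, squared magnitude).
* Filter edges are reflect-padded (three filter lengths); ERD/ERS trials
  are additionally reflect-padded by 2 s before the narrowband filtering
  and analytic transform, so neither filter transients nor the circular
  Hilbert computation contaminate the epoch.
* ERD/ERS per bin uses the squared analytic-signal envelope of the
  zero-phase order-2 bandpassed trial, averaged over trials, expressed as
  percent change against the -2-0 s baseline mean. The estimator is the
  standard band-power method; the display band of any figure is a view
  parameter, while the analysis alpha band is fixed at 8-13 Hz. One
  inherent artifact is worth knowing: a 1 Hz-wide zero-phase filter has
  ~1 s temporal resolution, so a task-onset power rise smears backwards
  into the last fraction of the baseline window and biases the whole map
  a few percent negative; strong effects dominate this easily, but very
  small ones should be judged against the baseline residual rather than
  against exactly zero.
* STFT: 1 s periodic Hann windows, 50% overlap, `floor((T - 1)/0.5) + 1`
  frames; a frame enters the EC or EO average only if it lies entirely
  inside one block. ROI alpha power is averaged across channels in the
  power domain *before* the dB transform.
* Epoch windows are half-open in samples (`[onset + start, onset + end)`),
  so a (-2, 10) s window at 200 Hz is exactly 2400 samples.
* Peak-to-peak rejection takes the maximum over the analyzed ROI's
  channels of the within-trial range; a trial is removed only when the
  range *strictly exceeds* the threshold. Rejection is ROI-scoped (the
  channel scope of the original screening is not fully specified); with
  the frontal-dominant blink model this means frontal/scalp analyses
  reject blink trials while posterior ROIs, where blinks are attenuated
  to ~1 uV, keep them.
* Friedman uses the tie-corrected chi-square statistic; `exact = TRUE`
  enumerates the within-subject rank-permutation null for small tables.
  Wilcoxon signed-rank p-values are exact (full sign-flip enumeration,
  ties included) for n <= 15 and use the tie-corrected normal
  approximation above. Post-hocs are two-sided over all ROI pairs with
  Bonferroni correction 0.05/6.
* EC/EO blocks are laid out contiguously and the inter-trial rest is
  drawn uniformly on [10, 15] s; neither the block spacing nor the rest
  distribution is pinned down by the protocol description, and nothing
  downstream depends on either choice.

## Problem sizes

The validation suite runs the full five-subject study (5 sessions x
(10 MA + 10 LC) trials each, 47 minutes of 31-channel 1 kHz data per
subject) for the headline decoding check, and reduced sizes elsewhere:
two-session subjects for effect-recovery checks, three-session subjects
for null calibration, and 6-minute resting runs for the SNR analyses.
These sizes were chosen so the whole suite exercises every stage at full
fidelity at least once while remaining comfortable to run on a laptop.

## Known limitations

* The 2-D exponential mixing reproduces orderings, not absolute
  topographies; do not interpret simulated microvolt values as
  physiological predictions.
* The EDF writer quantizes to 16 bits over each channel's amplitude range
  and truncates to whole seconds.
* `friedman_test(exact = TRUE)` is limited to tables with
  `factorial(k)^n <= 1e6` and no within-subject ties.
* The Ledoit-Wolf intensity shrinks toward `nu I`; when the true feature
  covariance genuinely equals that target the estimate is 1 (full
  shrinkage), which is optimal there but surprises intuitions trained on
  "shrinkage goes to zero with more data".
* Between-subject variability is modelled only as a lognormal jitter on
  the effect sizes (`subject_jitter`, default 0.08); real populations
  vary in ways the generator does not attempt to capture.
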