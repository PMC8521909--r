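---
title: "Methods: joint acoustic emissions and the knee health score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint acoustic emissions and the knee health score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jaescore)
```

## Scope and scientific setting

Joint acoustic emissions (JAEs) are the skin-measurable vibrations a knee
produces while it articulates. A healthy knee, with smooth cartilage and
normal synovial fluid, produces a broadband noise-like signal; an inflamed
knee — the motivating case is juvenile idiopathic arthritis — produces
periodic, high-energy transient clicks in each flexion/extension cycle,
believed to arise from increased internal friction. `jaescore` builds a
classification and monitoring pipeline on that contrast: segment each
recording into movement cycles, describe each cycle with short-time audio
features, classify cycles with leave-one-subject-out (LOSO) logistic
regression, and summarize each subject with a *joint health score* — the
mean predicted probability of the arthritic class over that subject's
cycles.

Because no patient recordings ship with the package, a synthetic-cohort
generator is a first-class, tested component: it defines the study
conditions under which every other stage is validated.

## The synthetic cohort generator

A recording session consists of a low-rate knee-angle trace (default
50 Hz, emulating an ankle-worn IMU) and one audio-rate acceleration channel
per accelerometer (default four channels per subject: two per knee, medial
and lateral). The movement protocol is ten unloaded flexion/extension
cycles at one cycle per 4 s; the angle swings smoothly between ~90° and
full extension with small seeded per-cycle jitter in period (relative SD
0.03) and range of motion (0.05), so segmentation is tested against
imperfect movement.

The audio model is deliberately minimal:

* **Background**: white Gaussian noise at the profile's RMS (default 1, in
  arbitrary acceleration units).
* **Clicks**: per cycle, a Poisson-distributed number of transients (mean
  `clicks_per_cycle`), each an exponentially decaying sinusoid with a 3 ms
  envelope time constant, carrier frequency drawn uniformly from 2–8 kHz,
  random onset phase within the cycle, and peak amplitude
  `click_amplitude` × noise RMS. Healthy profiles default to zero clicks;
  arthritic profiles default to 6 clicks per cycle at amplitude 10. The
  click morphology (decaying sinusoid) is this package's choice: the
  phenomenon being emulated is only characterized as spike-like transients
  with high-frequency content, so any transient with those properties
  serves.
* **Follow-up sessions**: generated from the arthritic profile with click
  rate and amplitude attenuated 5-fold, emulating a large reduction in
  clicking after successful treatment. Follow-up sessions carry an
  `"unknown"` group label and are never used for training.

The default audio rate is 25 kHz rather than the 100 kHz of
laboratory-grade hardware. The analysis band tops out at 10 kHz, so 25 kHz
preserves everything the features can see while keeping a 43-subject,
4-channel cohort comfortably in memory; the rate is a configuration knob
and the band-pass adapts (below) when it is reduced further.

Per-subject and per-channel RNG streams are derived by hashing
`(seed, subject_id, visit, channel)` into 32-bit sub-seeds, so cohorts are
bit-reproducible and adding subjects never perturbs existing waveforms.

**What the generator does *not* emulate** — and therefore what passing
tests cannot certify about real recordings: sensor transfer functions and
attachment variability, ambient and motion artifact beyond the band edges,
inter-subject anatomical variability, correlated noise between the two
channels of one knee, and any physiological relationship between click
statistics and disease severity beyond the monotone attenuation built into
the follow-up profile. The synthetic classes are, by construction, far more
cleanly separated than clinical populations: the pipeline reaches
near-ceiling accuracy on its own defaults, and those numbers characterize
the implementation (signal present → recovered; signal absent → chance),
not expected clinical performance.

## Preprocessing

**Band-pass filter.** A linear-phase windowed-sinc (Hamming) FIR band-pass
with default 250 Hz–10 kHz edges: the low edge rejects muscle sound and
low-frequency motion artifact, the high edge removes high-frequency
artifact while preserving the kHz range where click energy lives. The
order is `4·fs/low` rounded to even (400 taps at 25 kHz), applied by FFT
convolution with reflect-padding and group-delay compensation, so the
output is time-aligned and length-preserving. Any design meeting the
stop-band/pass-band checks in the test suite (≥ 40 dB at 50 Hz, ≤ 1 dB at
1 kHz, < 2 dB change on a second in-band application) is conforming. When
a configuration's sampling rate cannot represent the upper edge
(`high ≥ fs/2`), `jae_config()` clamps it to `0.45·fs` and warns —
reduced-rate desk configurations stay valid — while the low-level
`bandpass()` operation rejects such a band outright with a Nyquist error.

**Cycle segmentation.** Cycle boundaries come from the motion trace: the
angle is low-pass filtered at 5 Hz, and local minima (full flexion, the
start of each cycle) are detected with a minimum separation of half the
median inter-minimum distance, ties broken by the earliest index. Two
robustness rules handle edge effects: a session must contain at least one
*prominent* interior extension peak (rise and fall ≥ 25 % of the range of
motion on both sides) or segmentation fails — this rejects monotone,
cycle-free motion rather than inventing boundaries from filter ripple; and
a trailing fragment shorter than half the median cycle length is treated as
the final cycle's end boundary, not as a cycle. As a quality-control
cross-check the audio envelope (block-averaged |x| at the motion rate,
5 Hz low-passed) is correlated with the angle trace and the correlation is
attached to the segmentation result; the motion minima remain the sole
source of boundaries, because the original index-selection rule that
combined the two signals was never specified precisely enough to
reimplement. Indices are 1-based half-open `[start, end)`, the idiomatic
convention in R.

**Framing.** Each cycle is split into contiguous non-overlapping frames of
`round(0.4 s × fs)` samples; the remainder is discarded. At the protocol's
4 s cycles this gives 10 frames per cycle, wide enough to resolve the
low end of the analysis band yet numerous enough for per-cycle dispersion
statistics.

## Features

The registry fixes ten base features per frame. Time-domain features use
the raw frame: zero-crossing rate (sign changes per second), energy
(Σx²), RMS, and signal entropy (Shannon entropy, base 2, of the normalized
energy distribution over 32 equal subframes — low when energy concentrates
in a click). Spectral features use the one-sided magnitude spectrum of the
Hann-windowed frame: centroid (power-weighted mean frequency), spread
(power-weighted SD about the centroid), roll-off (frequency below which
85 % of power lies — the conventional percentile), spectral entropy
(base-2 Shannon entropy of the normalized power spectrum), flux (squared
difference of successive sum-normalized magnitude spectra, defined as 0
for a cycle's first frame, which has no predecessor), and spectral density
(mean power spectral density with periodogram scaling
`|X|²/(fs·Σw²)`, the natural reading of a "mean band power" feature).
All-zero frames return 0 for every spectral feature by convention, never
NaN.

Each base feature is summarized across a cycle's frames by mean,
population SD (n denominator — stated so tests are unambiguous) and
coefficient of variation `SD/(|mean| + 1e-12)` (the epsilon guards
division by a vanishing mean). With 10 base features × 3 statistics the
default matrix **X** has 30 feature columns. The study design this package
models used 49 descriptors per cycle, but the full list is not publicly
retrievable; the registry is
therefore an explicit stand-in, the documented extension point
(`extra_cycle_features`) accepts additional per-cycle functions, and every
downstream stage is dimension-agnostic — nothing assumes 30 or 49.

Standardization (zero mean, unit variance per column) is always fit on a
training set and applied to held-out rows with the training statistics;
zero-variance columns get an epsilon SD with a warning, mapping constant
columns to zeros.

## Classification and the joint health score

The logistic model is fitted by maximizing the Bernoulli log-likelihood
with BFGS (a quasi-Newton method) plus a damped Newton polish, using
analytic gradients; convergence is declared at gradient ∞-norm < 1e-6
(cap 500 BFGS + 100 Newton iterations; non-convergence returns the best
iterate with a warning). A ridge penalty of 1e-4 on the coefficients (not
the intercept) is the default because the synthetic cohorts are often
linearly separable, where the unpenalized MLE diverges; `ridge = 0`
recovers the pure MLE, and the unpenalized fit is verified against
`stats::glm` in the test suite.

LOSO evaluation removes all rows of one subject, standardizes the
remaining matrix, fits, then standardizes and scores the held-out rows
with the training statistics. Cycle label = 1 iff p > 0.5. The joint
health score is the mean of the subject's cycle probabilities; the subject
is called arthritic iff score > 0.5 — ties at exactly 0.5 go to healthy —
and a majority-of-cycle-labels call (even splits also to healthy) is
reported alongside, since both aggregation rules are in circulation for
this design. ROC curves sweep all unique cycle probabilities and AUC uses
the trapezoid rule; pROC serves as an independent cross-check in tests,
never as the implementation.

## Feature importance and the accuracy grid

With standardized inputs, coefficient magnitudes are directly comparable,
so importance ranking is a single fit on all baseline rows followed by
ordering on |βᵢ| (ties by column order). The input must actually be
standardized — the function verifies column means and variances and
refuses otherwise.

The accuracy grid answers a study-design question: how does subject-level
accuracy degrade with fewer top-ranked features (rows of the grid) and
fewer recorded cycles (columns)? For each k a full LOSO pass is run on the
top-k columns; for each held-out subject and cycle count m, up to
`perm_cap` unique m-subsets of the subject's rows are drawn (exhaustively
when there are no more than `perm_cap`; otherwise by rejection sampling
with a deterministic per-(subject, k, m) sub-seed), the subject is
classified from each subset's mean probability, and the cell averages the
resulting accuracy over subsets and subjects. Subjects' rows are pooled
across all channels when drawing subsets — the natural reading of testing
on all cycles from all microphones — and a subject with fewer than m rows
contributes its full row set. The cell at (k, all cycles) provably equals
the plain LOSO subject accuracy on the top-k columns, which the tests
assert. Note that accuracy as defined here is an ordinary proportion
correct: for a binary decision its floor under an uninformative model is
near 50 %, not near zero.

## Longitudinal tracking

Follow-up sessions are scored by a model trained on baseline rows only.
The default protocol additionally excludes the scored subject's own
baseline rows (`protocol = "loso"`), so the score contains no identity
leakage; `protocol = "cohort_exclusion"` instead trains once per subject
on all baseline subjects outside the follow-up cohort, reproducing the
simpler protocol of training on everyone not followed up. The paired drop
Δ = baseline − follow-up is tested with a one-tailed paired t-test using
the sample (n−1) SD; p is the upper Student-t tail at n−1 degrees of
freedom (10 pairs → 9 dof). Degenerate inputs are defined, not NaN:
all-zero deltas give t = 0, p = 0.5; zero-variance nonzero deltas give
t = ±∞, p ∈ {0, 1}, flagged.

## Numerical choices and degenerate inputs

* Seeds: all randomness flows from one integer seed through the 32-bit
  hash `jae_seed()`; cohorts, heatmaps and full pipeline runs are
  byte-reproducible (asserted by checksum in the tests).
* Epsilons: CoV denominator 1e-12; zero-variance standardization SD
  1e-12 (warned); Newton Hessian damping 1e-10 on the intercept.
* Tie-breaks: boundary-minima ties to the earliest index; ranking ties to
  column order; classification ties (score = 0.5, even label splits) to
  healthy.
* Error taxonomy: invalid arguments, segmentation failures, too-short
  cycles and invalid training sets raise classed conditions
  (`jae_invalid_argument`, `jae_segmentation_failure`,
  `jae_too_short_cycle`, `jae_invalid_training_set`) so callers can
  distinguish user error from data pathology.
* WAV export/import is a minimal mono float32/PCM16 RIFF implementation
  (no R WAV package is part of the package's dependency footprint); it is
  cross-checked against an independent implementation (scipy) in the
  tests, and float32 quantization perturbs downstream features only at
  the 1e-7 relative level.

## Problem sizes used in validation

The test suite and the acceptance script choose sizes that exercise every
code path at full fidelity where it matters and reduced scale elsewhere —
these are the package's validation conditions, stated here so they are
reproducible choices rather than incidental ones:

* Strong-effect recovery: 16 subjects (8 per class) at the full default
  design — 4 channels, ten 4 s cycles, 25 kHz, click amplitude 12 —
  expecting cycle accuracy ≥ 0.9 and perfect subject classification.
* Null recovery: ten 12-subject cohorts with click amplitude 0 (the two
  class generators then coincide distributionally) at 4 kHz with a
  clamped band, expecting mean cycle accuracy within 50 ± 10 %.
* Longitudinal: five seeds of a 10-subject arthritic / 8-healthy cohort
  with 5 follow-up pairs each at reduced scale, expecting every delta
  positive and p < 0.001; plus fixed-vector oracles for the t statistic.
* Accuracy grid: the strong cohort with the top 10 features and a
  100-subset cap per cell.
* The acceptance script runs the full default design: 25 arthritic + 18
  healthy subjects, 10 follow-up pairs, 4 × 10 cycles each at 25 kHz.
* White-noise spectral-entropy checks use long (32768-sample) frames:
  periodogram fluctuation costs a constant ≈ 0.6 bits of entropy, so the
  relative gap to the log₂(n_bins) ceiling shrinks with frame length and
  the flat-spectrum property is cleanly testable there.

## Known limitations

* The feature registry is a principled stand-in, not a reconstruction of
  the original 49-feature list; ranking results on real data would depend
  on the exact registry.
* Cycle boundaries rely on the motion trace alone; recordings with a
  missing or desynchronized IMU channel are out of scope (the audio
  envelope is used only as a QC number).
* The generator's clean class structure makes headline numbers
  near-ceiling; they validate the machinery, not clinical effect sizes.
* Follow-up timing (weeks vs. months) plays no computational role in the
  pipeline and is not modeled.
* Single sampling rate per cohort; resampling heterogeneous cohorts is
  out of scope, as are streaming operation and artifact rejection beyond
  the band-pass filter.
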