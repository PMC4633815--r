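---
title: "Simulating and analysing a cross-modal cueing infant ERP experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a cross-modal cueing infant ERP experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpcue)
```

## The experiment being modelled

`erpcue` implements, end to end, the computational analysis of a
cross-modal cueing EEG experiment in 12-month-old infants. Two arbitrary
sounds are first associated with two visual categories (faces, flowers).
In the test phase each trial shows a forward mask for 1000 ms, then a
briefly presented masked target (66, 100 or 133 ms — around the infant
perceptual threshold), then a backward mask. On two thirds of trials one
of the sounds precedes the target by 500 ms; the sound predicts its
associated category 75% of the time (*valid* trials) and the other
category 25% of the time (*invalid*). The remaining third are *no-cue*
baseline trials. The analysis asks how prior expectations modulate three
occipito-temporal ERP components: an early positivity ("P1", which folds
in the putative N290), the infant P400, and the late slow wave (LSW), a
sustained negativity linked to novelty and conscious access.

No real recordings ship with the package (and none are publicly
deposited), so a first-class synthetic-data module generates designs and
EEG with the statistical structure the analysis assumes. Every
downstream stage — preprocessing, component extraction, inference — is
agnostic about where its input came from.

## Trial design generation

`design_spec()` holds the probabilistic structure: P(no cue) = 1/3,
P(valid | cued) = 0.75, blocks of nine test trials with exactly three
trials of each duration per block, ten familiarization trials, and the
timeline constants (forward mask 1000 ms; cue onset 500 ms after mask
onset, duration 250 ms, hence cue onset 500 ms before target onset).

Two allocation modes exist. The default, `"exact"`, fixes the
per-condition counts at their rounded expectations for the session and
shuffles only the order; with 90 test trials that gives 30 no-cue, 45
valid and 15 invalid trials every session. This stabilises small-session
tests and matches the spirit of drawing trials "from a matrix of all
conditions". The `"iid"` mode draws each trial independently and is used
where genuine sampling variability matters (e.g. the error-rate
simulations). The exact constraint matrix of the original procedure is
unpublished; we constrain only the duration balance within blocks and the
global condition counts.

One timeline constant is deliberately exposed rather than fixed:
`backward_mask_total_ms` (default 1800 ms) sets the combined
target-plus-backward-mask span, the backward mask lasting that span minus
the target duration. Published descriptions of the paradigm are
internally inconsistent about this span (1800 vs 1700 ± 33 ms), and
nothing downstream depends on it — epochs end 1700 ms after target
onset either way — so it is a configuration value, not a guess.

## The synthetic EEG generator

`simulate_subject_epochs()` builds one epoch per design trial on the
canonical time axis (below) as

*epoch = condition kernel + 1/f noise + (occasional) artifact transient.*

**Component kernels.** Each component is a Gaussian bump in time,
truncated at ±3σ (the field publishes no waveform model, and a smooth
unimodal bump is the minimal shape with a defined support and peak).
Defaults: P1 at 240 ms (σ 25 ms, base 6 µV), P400 at 450 ms (σ 40 ms,
base 5 µV), LSW at 1070 ms (σ 90 ms, base −5 µV). Condition effects
enter as amplitude offsets in the direction the analysis is meant to
recover: P1 +3 µV for valid targets; P400 +2 µV for faces and +2 µV for
cued (valid or invalid) trials; LSW −2 µV for faces and −3 µV for
invalid targets. Channels see the bump through a Gaussian spatial
profile centred on the occipital ROI centroid (width 0.6 unit-sphere
distance), so posterior electrodes carry most of the signal. A
per-subject, per-component amplitude jitter (σ 1 µV) provides
between-subject variability; it is drawn once per subject, so it cancels
exactly in within-subject contrasts and contributes only to realistic
subject-level spread.

**Noise.** Background activity is Gaussian 1/f noise (power exponent
1.0), synthesized per channel by spectral shaping of white noise and
scaled to 10 µV RMS — a conventional rendering of the dominant low-
frequency character of infant EEG. Channels are independent; real scalp
noise is spatially correlated, which means ROI averaging gains more SNR
here than it would in vivo (see *Limitations*).

**Artifacts and look-away.** With probability 0.25 a trial receives a
high-amplitude transient (Gaussian, σ 20 ms, random latency). A quarter
of these are "large": 48–90 channels hit at 420–700 µV, guaranteed to
trip the ±400 µV screen on more than 35% of channels and lose the trial.
The rest are "small": 2–12 channels at 150–390 µV, straddling the 120 µV
smoothing threshold so the interpolation and smoothing stages do real
work without costing the trial. Look-away is Bernoulli per trial with
p = 22.2/90.

**Calibration.** These rates are not arbitrary: with 90 test trials the
expected rejections are 22.2 look-away trials and 90 × 0.25 × 0.25 ≈ 4.2
artifact trials, leaving 63.6 surviving epochs on average, splitting by
the design marginals into per-condition means of about 15.9 (valid),
10.6 (no-cue) and 5.3 (invalid) per category — the calibration targets
returned by `calibration_targets()`. `simulate_surviving_counts()`
checks this at the count level across simulated subjects without paying
for waveforms.

## The canonical time axis

Epochs span −150 ms to +1700 ms around target onset at 250 Hz. Because
1850 ms is not an integer multiple of the 4 ms step, the axis holds 462
samples at t_k = −150 + 4k ms (k = 0…461, last sample 1694 ms). When
cutting epochs from a continuous recording, the −150 ms edge maps to 37
samples before the event (37.5 floored). All window-to-sample
conversions are inclusive on both ends at nearest-sample resolution; the
180–300 ms window, for instance, covers exactly 30 samples
(182–298 ms). The baseline interval is half-open, [−150, 0) ms.

## Preprocessing chain

`run_preprocessing()` applies, in order: average re-reference; zero-phase
0.2–20 Hz band-pass; (for continuous input) segmentation; look-away
rejection; per-epoch contaminated-channel detection and interpolation;
rejection of trials with more than 35% contaminated channels; ±120 µV
temporal smoothing; baseline correction. Numerical choices worth
recording:

* **Filter realization.** Only the cutoffs are prescribed, so the filter
  is ours to design: order-2 Butterworth high- and low-pass magnitude
  responses applied with zero phase in the frequency domain on a
  reflection-padded segment. This has exactly the gain a
  forward–backward IIR pass would have (≈0.94 at 10 Hz, 0.059 at 40 Hz,
  DC removed) with none of its edge transients — which matters when
  high-passing 1.85 s epochs at 0.2 Hz, where IIR start-up artifacts
  would dwarf the signal.
* **Channel screening.** A channel is contaminated if |v| exceeds
  400 µV at any sample, or if its peak-to-peak range within any
  10-sample sliding window exceeds 400 µV ("local deviation" is not
  defined in print; peak-to-peak range is the natural operationalisation
  of a windowed deviation). All comparisons are strict at the
  thresholds, reading "exceeding" and "more than" literally.
* **Interpolation.** Flagged channels are replaced by the
  inverse-distance-weighted mean of the 4 nearest clean electrodes in
  3-D montage coordinates — a concrete rendering of "linear
  interpolation from the nearest electrodes". The screen runs once per
  epoch, before interpolation, in a single pass (the published stage
  order within the artifact step is ambiguous; a single pass is the
  simplest consistent reading).
* **Temporal smoothing.** The published infant artifact-correction
  method relies on an unpublished smoothing matrix; we implement the
  contract it serves with a transparent scheme: samples exceeding
  ±120 µV are replaced by a 5-sample moving average of the signal
  clipped to ±120 µV. Replacements are bounded by the threshold, samples
  below threshold are untouched, and the operation is exactly idempotent.
  It is a faithful-in-spirit stand-in, not a reimplementation of the
  original matrix.
* **Montage.** No vendor electrode file is distributed; the 128-channel
  geometry is synthetic (a Fibonacci spiral over the upper hemisphere),
  with the nine ROI labels TP9, P9, PO7, O1, OZ, O2, PO8, P10, TP10
  assigned to the most posterior band. Interpolation and the spatial
  kernel profile only need plausible relative distances, which this
  provides.

A subject lacking at least two surviving trials in any of the six
category × cue conditions is flagged excluded, mirroring the study's
inclusion rule. The QC report conserves counts by construction:
look-away + artifact-rejected + surviving = generated, at every stage.

## Component extraction

Per-condition ERPs are arithmetic epoch means; the ROI series is the
unweighted mean over the nine occipito-temporal electrodes; component
amplitudes are window means over 180–300, 360–540 and 860–1280 ms.
Because all three operations are linear, window-mean extraction commutes
with averaging across epochs and subjects — a property the tests
exercise. For the omnibus ANOVA the LSW (a negativity) is sign-inverted
so its modulation is comparable with the positive components; post-hoc
LSW contrasts are reported on the inverted scale and flagged as such.
Whether the original cluster analysis ran on the ROI average or
per-electrode is not stated; we analyse the ROI-averaged series, which
matches the ERP figures the windows were derived from, and note it here
rather than silently assuming exclusivity.

`find_component_windows()` reproduces the exploratory step that
motivated the windows (extrema of the collapsed grand average) but never
overrides the configured windows.

## Inference layer

**Repeated-measures ANOVA.** The 3 (component) × 2 (category) × 2
(validity) all-within design is fitted by the classical balanced
sums-of-squares decomposition, each effect tested against its
subject-interaction error term: with n subjects the component main
effect has df (2, 2(n−1)) — (2, 54) at n = 28. Uncorrected F tests are
the default (matching the plain printed df); Greenhouse–Geisser
correction is available (`sphericity = "GG"`). The test suite checks the
engine against an independent hand-coded decomposition to 10⁻⁸.

**Cluster-based permutation test.** The multiple-comparison-controlled
contrast over the whole epoch. Per-sample paired t statistics are
thresholded at the two-tailed critical value for p = 0.05; maximal runs
of consecutive supra-threshold samples form clusters (positive and
negative t separately); each cluster's statistic is the sum of its t
values. The null distribution is the maximum absolute cluster statistic
over random within-subject condition relabelings, implemented as sign
flips of the per-subject difference series — mathematically equivalent
for a paired design. The Monte-Carlo p is N/n_perm, the fraction of null
maxima at least as large as the observed |statistic| (the printed
estimator; it can return an optimistic 0 when no null maximum reaches
the observed value, a known caveat of this estimator that the exact mode
sidesteps). Sidedness is not stated in print; we use the two-sided max
over |signed cluster sums|, consistent with the two-tailed post-hocs.
Samples with zero variance across subjects get t = 0 and cannot enter a
cluster (conservative). `cluster_test_exact()` enumerates all 2ⁿ sign
patterns for n ≤ 14 and serves as the ground-truth oracle for the
Monte-Carlo path.

**Calibration.** `fwer_simulation()` estimates the family-wise
false-positive rate on null data (both "conditions" drawn from the same
Gaussian process). Under exchangeability the sign-flip null is exact, so
the rate should not exceed the nominal 0.05 beyond binomial error —
the property the acceptance checks measure rather than assume.

## Problem sizes used by the checks

The shipped tests and the acceptance script choose sizes that make the
statistics meaningful at desk scale: the oracle-equivalence check runs
12 subjects × 20 samples against full 2¹² enumeration; the in-suite
error-rate check uses 500 null datasets of 16 subjects × 231 samples at
500 permutations; the standalone acceptance script runs the full-size
calibration (500 datasets, 28 subjects, 462 samples, 1000 permutations);
and the effect-recovery check simulates the complete 28-subject cohort
through the whole pipeline with 3000-permutation cluster tests. The
cohort sizes mirror the study (28 infants, 10 blocks of 9 trials).

## Limitations

The generator is a statistical emulator, not a biophysical one: noise is
spatially independent 1/f (no alpha rhythm, no spatially coherent
movement artifacts, no electrode drift); look-away is Bernoulli rather
than behaviourally clustered; kernels are stationary Gaussians with no
latency jitter. Passing tests therefore demonstrate that the *analysis
chain* is correct and calibrated — marginals, thresholds, error rates,
effect-direction recovery — not that it would extract these effects from
any particular real infant dataset. The smoothing stage is a documented
stand-in for an unpublished method, and the montage geometry is
synthetic; both are flagged in their documentation.
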