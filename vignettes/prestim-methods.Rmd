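---
title: "Prestimulus time and feedback ERP analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prestimulus time and feedback ERP analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prestim)
```

## The scientific problem

In a two-option gambling task, a subject repeatedly chooses between a large
bet (left square, stake `X`) and a small bet (right square, stake 5); one
second after the choice the squares turn green (gain) or red (loss) with
equal probability. The ratio `E = X / 5` (`reward_parameter()`) indexes the
risk level of a block; blocks with `E` of 5, 7 and 10 correspond to stakes
of 25, 35 and 50.

Two electrophysiological quantities are of interest at the frontal-midline
electrode Fz, which indexes medial-frontal-cortex activity:

* **Prestimulus time (PT).** Before the choice, the average EEG of trials
  in which the subject is about to pick the big bet diverges negatively
  from the average of small-bet trials. The PT is the time before the
  decision at which the two condition-average waveforms last intersect and
  then remain separated through the moment of choice. It grows with `E`.
* **Feedback delta amplitude (Δ).** About 232 ms after the outcome is
  revealed, loss and gain trials evoke a medial-frontal component of
  different amplitude; Δ is the absolute difference between the gain and
  loss group-mean amplitudes at that latency, and it also grows with `E`.

Because raw recordings of this kind are not publicly distributable, the
package ships a synthetic-data generator with known ground truth; every
stage of the pipeline is exercised and validated against that ground
truth.

## The synthetic generator

`generate_session()` builds a continuous multichannel recording (default
64-channel cap: 63 ten-ten EEG sites plus a vertical EOG channel, 500 Hz)
of `n_trials` three-second trials: the choice happens 1 s into the trial
and feedback follows exactly 1 s later. It injects:

* a **pre-decision divergence**: on left-choice trials only, a linear ramp
  at frontal sites starting `divergence_onset` ms before the choice and
  reaching `divergence_amplitude` µV at Fz at the moment of choice;
* a **feedback component**: a Gaussian-windowed deflection (SD 50 ms)
  peaking `mfn_latency` ms (default 232) after feedback, with separate
  amplitudes for loss and gain trials and valence-dependent topography
  (gain anterior-focused, loss posterior-focused);
* **1/f background noise** (RMS 5 µV per channel by default) shaped with a
  first-order 0.5 Hz high-pass that emulates the acquisition amplifier —
  without it, sub-0.1 Hz drift dominates the variance and swamps every
  correlation computed on the continuous signal;
* **blinks**: Poisson-scheduled biphasic 150 ms transients of 150–400 µV
  on VEOG, propagated to the scalp with a front-to-back decaying profile
  (~45% of VEOG at the frontal pole, 15–20% at Fz), so that they exceed
  the 100 µV blink-labeling criterion on VEOG.

Template scalp maps are constructed with zero spatial mean over the EEG
channels and unit weight at Fz. Reference-free surface potentials sum to
zero over a closed surface, so this makes the templates pass unchanged
through common-average referencing, and the configured amplitudes read
directly off the Fz trace of the processed averages.

Where the underlying study reports no value, defaults were fixed once at
physiologically plausible scales and not revisited: the divergence
amplitude deepens with `E` (−6, −9, −12 µV for `E` = 5, 7, 10 — a larger
expected reward produces a larger frontal negativity, on the scale of
readiness potentials), the feedback-component width is 50 ms (SD), and the
per-block feedback amplitudes are the loss/gain pairs (−0.34, +0.37),
(+0.52, +2.04), (+0.32, +2.15) µV, whose differences are 0.71, 1.52 and
1.83 µV. `generate_cohort()` adds between-subject normal jitter: onset SD
9 ms, amplitude SD 0.1 µV, latency SD 5 ms.

What the generator does **not** emulate: realistic volume conduction (maps
are parametric Gaussians, not forward-model projections), spatially
correlated background noise, non-ocular artifacts (muscle, line noise,
electrode drift), overlapping ERP components common to both conditions,
and any trial-to-trial amplitude variability beyond the between-subject
jitter. Passing recovery tests on this generator therefore demonstrates
the correctness and calibration of the estimators under the stated noise
model, not performance on arbitrary real recordings.

## The preprocessing chain

`preprocess_session()` runs, in order: ocular-component removal on the
continuous recording, epoch extraction, baseline correction, amplitude
rejection, per-condition averaging, zero-phase low-pass filtering of the
averages, and common-average referencing. The stage order actually run is
recorded in every pipeline report.

* **Baseline correction** (`baseline_correct()`): the constant method —
  per trial and channel the mean over the baseline window is subtracted.
  Decision-locked epochs use (−500, −400] ms (a segment that precedes any
  plausible divergence onset), feedback-locked epochs (−100, 0] ms.
* **Ocular removal** (`remove_ocular()`): the EEG channels are whitened
  and decomposed with a fixed-point symmetric ICA (tanh contrast,
  component count = channel count); every component whose absolute Pearson
  correlation with the VEOG trace exceeds 0.7 is zeroed before
  reconstruction. Convergence of the rotation is immaterial for
  reconstruction (any orthonormal rotation of the whitened space
  round-trips the data), so the iteration cap is modest; rank-deficient
  input raises an error naming the condition.
* **Epoching** (`extract_epochs()`): the sample at t = 0 is the marker
  sample. Epoch windows include both endpoints, so a (−500, 0] ms window
  at 500 Hz has 251 samples; *sub-interval* selections on an existing
  epoch axis (baseline and artifact-scan windows) are half-open
  (start, end], which keeps ownership of shared boundary samples
  unambiguous. Markers too close to the recording edge yield trials
  flagged `"edge"` rather than silent drops.
* **Rejection** (`reject_epochs()`): trials with any EEG-channel sample
  exceeding ±100 µV inside the (−200, 500] ms scan window are flagged
  `"amplitude"`. The EOG channel is excluded — it is supposed to exceed
  the threshold during blinks.
* **Averaging** (`average_epochs()`): the pointwise arithmetic mean over
  kept trials of one condition, with the trial count `n` recorded.
* **Filtering** (`lowpass_filter()`): 4th-order Butterworth, 30 Hz,
  applied forward-backward. Zero phase matters because PT and the
  feedback latency are latency statistics; causal filtering would bias
  them. Applied to the evoked averages (linear, so the order relative to
  averaging is immaterial for the result; filtering 4 averages is ~40×
  cheaper than filtering 300 trials).
* **Referencing** (`average_reference()`): common average over the EEG
  channels; idempotent, EOG left out of the mean.

## The PT statistic

`compute_pt()` implements the last-intersection definition literally: with
d(t) the difference of the two condition averages at Fz, the crossing time
t\* is the latest t < 0 at which d changes sign between consecutive
samples (linearly interpolated) or coincides with zero within tolerance;
PT = −t\*. Separation must persist: the sign of d is constant on
(t\*, 0]. If d never crosses but is single-signed, the waveforms are
separated for the whole window — PT equals the window length and
`persistence_ok` is `FALSE`; an identically zero difference is an error
("no separation"). The implementation is property-tested against an
independent exhaustive scan over every adjacent sample pair.

**Why the cohort analysis does not apply the last-crossing per subject.**
At realistic single-subject noise (5 µV RMS background, ~150 trials per
condition) the pre-onset difference is pure low-frequency noise whose last
zero-crossing wanders by tens of milliseconds: in pilot simulations the
per-subject last-crossing had an SD of 45–85 ms and a +30–60 ms group
bias, because slow noise can keep the ramp's sign long before the true
onset. The positive bias scales with the noise correlation length, not
with the noise amplitude, so averaging subjects does not remove it.
`analyze_block()` therefore derives per-subject PT values by a matched
filter (`fit_divergence_onset()`): the subject's difference waveform is
projected onto a family of linear-ramp templates parameterized by onset,
and the onset maximizing the normalized inner product is that subject's
PT. The fit integrates over the whole ramp and is unbiased for ramp-shaped
divergences (the normalized template autocorrelation peaks at the true
onset), with a per-subject SD of ~13–15 ms under the default cohort
conditions. The literal grand-average last-crossing is still computed and
reported (`pt_grand`), and `pt_mode = "independent"` restores the
per-subject last-crossing for users who want the raw statistic. Group
summaries are the mean ± SD of the per-subject values, and between-block
differences are tested by label-shuffling permutation (10,000 draws).

## Feedback latency and delta amplitude

The feedback-component measurement latency is estimated from grand-average
loss/gain differences. Two choices reduce noise-induced bias:

* **Collapsed localizer**: the measurement latency is estimated on the
  difference pooled over *all* blocks and subjects, then applied to every
  block — the standard way to avoid block-level selection bias, and
  appropriate here because the component latency is common across blocks.
* **Fractional-area latency** (`fractional_area_latency()`, default): the
  half-area point of |d(t)| within the 150–350 ms window. Peak picking on
  a noisy difference is biased toward whichever region happens to carry
  more noise (and baseline-corrected 1/f noise grows in variance across
  the epoch, tilting the argmax late); the area integral averages the
  noise out. In calibration simulations at the default cohort settings the
  pooled fractional-area latency has an RMSE of ~3 ms versus ~9 ms for the
  pooled argmax. The literal windowed argmax (`mfn_latency()`, ties to
  the earliest sample, boundary flagged) is reported per block as the
  descriptive peak time.

Per-subject loss and gain amplitudes are, by default, centered
least-squares projections of each subject's waveform onto the pooled
grand-average component shape, scaled so the coefficient reads as the peak
amplitude in µV. Unlike the classic mean amplitude over a fixed window
(also available, `amp_method = "mean"`), the projection does not
under-read a peaked component by the window's attenuation factor, at the
cost of ~10% more variance; on signal-free calibration cohorts the two
have per-subject SDs of 0.375 and 0.345 µV for the loss−gain difference
(group-of-12 SD ≈ 0.10 µV). The group delta is Δ = |mean gain − mean loss|, which
is exactly how the per-condition group means relate to the printed delta
row of the study design the generator mirrors. Loss vs gain within a block
is tested with a paired sign-flip permutation test; between-block delta
differences with the unpaired label-shuffling test.

## Numerical and design choices

* Time is stored in ms; t = 0 is the marker sample. Sampling rate defaults
  to 500 Hz (all configured latencies fall on the 2 ms grid).
* All stochastic steps take explicit seeds; cohort subject k of block b
  uses `seed + 10000·b + k`, so any subject can be regenerated alone.
* Permutation p-values use the add-one estimator (1 + #{|T\*| ≥ |T|}) /
  (n\_perm + 1), so the smallest attainable p at 10,000 draws is ~1e−4.
* The PT separation tolerance defaults to 1e−9 µV on the filtered
  averages; it is exposed because "complete separation" is
  noise-level-dependent in real data.
* Scalp maps use inverse-distance-squared interpolation inside the convex
  hull of the electrodes, nearest-electrode extrapolation outside it, and
  an NA mask outside the unit head circle.
* Degenerate inputs fail loudly: zero kept trials for a condition, empty
  baseline or scan windows, latencies off the time axis, rank-deficient
  data in the ICA, fewer than 2 subjects in a group test.

## Problem sizes used in the test-suite

The bundled recovery studies run 3 blocks × 12 subjects × 300 trials at a
19-channel 10–20 montage (plus VEOG) with blinks disabled and the ocular
stage off; PT and Δ are single-channel (Fz) statistics, so channel count
does not affect them, and the ocular stage is validated separately on
blink-bearing fixtures. At these sizes the measurement-noise floor for the
group delta is ~0.09 µV (SD), so individual block recoveries are expected
within ~±0.2 µV of the configured values; the PT group means recover
within ~±10 ms.

## Known limitations

* The matched-filter PT assumes a ramp-like divergence anchored at the
  decision; a divergence that plateaus early would bias the fitted onset.
* The ICA ocular stage assumes blink activity is captured by at most a few
  components with high EOG correlation; saccades or partially correlated
  components below the 0.7 gate pass through.
* EDF+ support covers the package's own label grammar and 16-bit
  continuous recordings with one sampling rate across data channels;
  annotation durations (TAL duration fields) are not parsed.
* The permutation tests treat subjects as exchangeable units; no
  hierarchical (trial-level) inference is attempted.
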