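---
title: "Methods: click detection from ECoG high-gamma activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: click detection from ECoG high-gamma activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clickbci)
```

## The problem

A "brain click" is a discrete command produced by detecting an attempted
movement — here a brief hand grasp — from electrocorticographic (ECoG)
signals recorded over sensorimotor cortex. A reliable click is enough to
drive a switch-scanning speller: rows and then columns of a key grid are
highlighted in turn, and the user selects by timing a click to the highlight,
so two clicks type one letter. This package implements the full offline
pipeline — spectral features, trial labeling, a recurrent classifier, click
post-processing, a closed-loop speller simulator, and the associated
evaluation statistics — together with a synthetic ECoG generator, so that
every stage can be developed and tested without access to patient recordings.

## Signal model and features

Raw signals are sampled at 1 kHz on up to 128 channels. Features are computed
over 256 ms windows advanced in 100 ms steps: each window is tapered (Hann by
default), Fourier transformed, and the per-bin power is log-transformed. Each
bin's log-power is z-scored against *calibration statistics* — the
per-channel, per-bin mean and standard deviation estimated from a resting
recording (60 s by convention) at the same framing — and the z-scores of the
bins whose center frequency lies in the high-gamma band (110–170 Hz,
inclusive) are summed per channel. The result is one 1-per-channel feature
vector every 100 ms.

Numerical choices that the field's description of an "FFT filter" leaves
open, and how this implementation pins them (each is recorded in
`spectral_config()` so a strict alternative can be selected):

* **Taper.** Hann, the conventional choice for short biosignal frames;
  `taper = "rectangular"` is available.
* **Log base.** Natural log; the base only rescales z-scores uniformly.
* **Band edges.** A bin belongs to the band iff `110 <= f <= 170` (closed on
  both ends). At the default 256-sample window the bin spacing is ~3.9 Hz and
  no bin falls exactly on an edge.
* **Normalization order.** z-score each in-band bin, then sum
  (`"z_then_sum"`, the default); the alternative reading — sum raw in-band
  log-powers, then z-score the sum — is available as `"sum_then_z"`.
* **Degenerate channels.** Calibration standard deviations are floored at
  `sd_floor` (default 1e-6) with a warning, so constant synthetic channels
  cannot produce infinities.
* **Timestamps.** A frame is stamped with its window's trailing (right) edge
  — the moment it becomes available — matching the convention that a
  classified sequence carries the label of its leading edge.

Streaming and whole-recording processing are the same arithmetic on the same
windows, so `packetized_features()` is bit-identical to `stream_features()`
for any packetization; the test suite asserts this.

## Trial labeling and shift warping

Training data comes from cued trials: a 100 ms Go cue followed by an
inter-stimulus interval drawn uniformly between bounds (3000–4500 ms by
default) to prevent anticipation. The participant-analog reacts after a
per-trial delay, so cue-aligned trials are misaligned by that delay. The
realignment model is deliberately *shift-only*: one integer frame shift per
trial, applied identically across all channels, fit by coordinate ascent —
align every trial's high-gamma trace (over a subset of strongly modulated
channels) to the cross-trial average template by maximizing summed Pearson
correlation, re-average, and repeat (at most 50 sweeps, shifts within ±5
frames, ties toward the smaller shift). Because the synthetic generator
applies one delay to the whole burst, those delays are exactly the quantity
shift warping is meant to recover, and the suite asserts recovery to within
one frame beyond the unavoidable ±0.5-frame quantization.

Grasp labels are then assigned to frames whose timestamps fall between and
including `onset + shift` and `offset + shift` relative to each cue; all
other frames are rest. The modulation onset and offset are estimated from
the aligned trial-average trace as the first and last crossings of 50% of
the peak elevation above the pre-cue median (`estimate_onset_offset()`), an
automated surrogate for determining them by visual inspection; a mandatory
override path pins externally chosen values (for example 0.3 s and 1.1 s
after the cue, an 800 ms grasp interval) verbatim. The estimator is the
default in the end-to-end pipeline for a reason worth stating: frames carry
trailing-edge timestamps, so the trace of a burst beginning ~300 ms
post-cue rises at ~0.55 s in frame time, and labels should follow the trace
(as they do when the window is determined from the traces themselves), not
the nominal movement time.

Cross-validation folds are built the way a time series demands: the labeled
stream is cut into `k = 10` contiguous spans containing equal numbers of
grasp frames (±1), and within each fold rest frames are randomly downsampled
(seeded) to match the grasp count. Downsampling removes only rest frames.
Contiguity bounds leakage between training and validation data to the fold
boundaries.

## The classifier

A many-to-one recurrent network maps 1 s of feature history (10 frames) to
rest/grasp probabilities: an LSTM layer with 25 hidden units, a
fully-connected layer of 10 units with eLU activation, and a 2-unit softmax.
Training uses categorical cross-entropy, Adam (learning rate 1e-3, the
optimizer's standard default — the rate is exposed in `model_config()`),
45-sample batches, 75 epochs, 30% dropout, and He-normal initialization of
all weight matrices including the recurrent ones. Dropout is applied to the
LSTM output and the FC1 output, not to recurrent connections. The forward
pass, backpropagation through time (including input gradients, which the
saliency module needs), and Adam are implemented in base R with batched
matrix operations; gradient correctness is checked against central
differences in the development workflow and the model trains to high accuracy
on separable synthetic data in seconds on one CPU.

Under the standard single-bias LSTM parameterization the architecture has
`4*((d+25)*25+25) + (25*10+10) + (10*2+2)` trainable parameters — 15,682 at
d = 128 channels, 5,682 at d = 8. `n_parameters()` reports this count.

Until the 10-frame history buffer is full a stream emits rest by convention,
so no click-relevant output exists before 1 s of data. Prediction is
deterministic, and batch versus streaming evaluation differ only by BLAS
summation order (equal to ~1e-12).

## Click detection

Each per-100 ms classification enters a vote ring buffer of length `window`
(10 for the communication board, 7 for the speller); a click fires when the
grasp votes in the buffer reach `threshold`, implemented as `>=` so that the
all-window conditions (10-of-10, 7-of-7) are satisfiable. Every click starts
a 1 s lock-out. Two choices the prose description leaves open are made
explicit and configurable:

* the vote buffer is **cleared on click**, preventing an immediate re-fire
  the moment the lock-out expires (which would produce multiple clicks from
  one long grasp), and
* votes arriving **during lock-out are discarded**, not queued.

An exhaustive test equates the detector with a brute-force sliding-window
oracle over every binary sequence of length 12 and every threshold ≤ window
≤ 4, with lock-out interacting. The minimum latency from the onset of grasp
classifications to a click is `threshold × 100 ms` — 400 ms at the speller's
4-vote threshold — with classifications stamped at the end of the packet
that produced them. Offline simulation adds a constant 200 ms display delay
to model the on-screen click.

For retraining from spelling sessions (where there is no Go cue),
`harvest_training_from_spelling()` labels around movement onsets instead,
excludes any grasp occurring < 3 s (the minimum jittered ISI) after its
predecessor, and removes — rather than labels as rest — the data around
excluded grasps.

## Speller simulator and user model

The switch-scanning machine is deterministic: three pre-selection steps
start each row-scanning cycle and one starts each column cycle (at the same
0.67 steps/s rate — only one rate is specified, and pre-selection exists to
give preparation time); clicks landing on a pre-selection step are ignored.
Selecting a row enters its column scan; selecting a key executes it and
restarts the cycle. Wrong output sets a pending-error flag that the simulated
user resolves by targeting DEL (or A-DEL after a wrong autocompleted word,
which deletes the whole word). ENTER on a completed prompt finalizes the
sentence.

The default layout (word-suggestion row, letter-suggestion row, alphabet,
controls) is a surrogate — the machine is fully layout-driven so any grid can
be pinned — and autocomplete is a deterministic word/letter frequency engine
over a small packaged table, standing behind the same interface an external
language-model service would use.

The behavioral user model reacts to a highlight after a uniform 150–450 ms
latency (chosen to keep clicks inside the 1.5 s true-positive window at the
default scan rate; the real participant's distribution is unknown) and
mis-aims with probability `error_rate`. Closed-loop sessions couple this
user to an oracle or stochastic detector; model-in-the-loop evaluation
synthesizes the session's continuous recording from the logged grasp onsets
and runs the full offline pipeline over it (`run_experiment()`), mirroring
offline simulation practice.

## Metrics and statistics

A click is a true positive if it appears on screen within 1.5 s (inclusive)
after an attempted-grasp onset; matching is greedy earliest-click-first with
one click per grasp (the lock-out makes competing clicks rare). Sensitivity
is `N_tp / N_grasps × 100%`; TPF and FPF are counts per minute of session
time. Latencies are summarized from movement onset to algorithmic detection
and to on-screen click. Spelling rates use position-exact matching of the
final text against the prompt (CCPM, CWPM), with WCPM counting wrong
characters output during the session; words are whitespace-delimited.

Confidence intervals are bias-corrected and accelerated (BCa) bootstrap
intervals of the mean (10,000 replicates by default, jackknife acceleration,
seeded); a coverage simulation in the suite checks 95% ± 3 points on normal
samples. Group comparisons use the two-sided Wilcoxon rank-sum test in its
normal approximation with tie and continuity corrections, reporting the z
statistic (matching the convention in which reported "W" values are
z-scaled), cross-checked against `stats::wilcox.test`; families of
comparisons are Holm-adjusted.

## Channel saliency

Integrated gradients attribute the grasp-class output of a trained model to
each element of its 10 × channels input history. The baseline is the
all-zero feature history — for z-scored features, zero is the rest-state
expectation — and the attribution target is the pre-softmax grasp score
(both configurable; neither is externally specified). The path integral uses
a trapezoid rule (64 points by default); completeness — attributions summing
to `F(x) − F(baseline)` — holds within 1% at 256 steps and exactly for
linear maps, both asserted in the suite. Saliency per channel is the L2 norm
of the attribution map across the 10 history steps, averaged over all
grasp-labeled validation samples of all cross-validated models (and over
repeated retrainings, which reduces the variance contributed by random
initialization), then min-max normalized to [0, 1]. Channels not fed to a
model receive no saliency entry.

## What the synthetic generator does and does not emulate

The generator produces 1/f-shaped Gaussian background noise on every
channel; during each grasp burst it adds independent band-limited
(110–170 Hz) noise on the hand channels, scaled so in-band power rises by
`hg_effect²` (amplitude gain `hg_effect`, default 2), with 50 ms cosine
ramps over an 800 ms burst. Cue timing, ISI jitter, reaction delays and the
optional 10–30 Hz ERD/ERS confound (power suppression around movement,
rebound after) follow the study conditions listed above. This reproduces the
statistical structure the pipeline *assumes*: stationary rest, a
band-limited multiplicative grasp effect, a per-trial shift common to all
channels.

It does not emulate electrode-specific spectra, cross-channel correlation,
line noise or movement artifacts, non-stationary baselines, day-to-day
drift, or any biophysics. Passing tests therefore demonstrate that the
pipeline's machinery is correct under its own assumptions — not that the
numerical performance reported on any real participant would be reproduced;
real-data headline numbers depend on recordings that are not publicly
deposited.

## Problem sizes used by the test and acceptance suites

Tests run the full pipeline at reduced scale, chosen as the smallest sizes
at which each property is meaningfully exercised: 8 channels with 2 hand
channels (preserving the ~1/10 informative-channel fraction of a 128-channel
grid with a 12-channel hand-knob subset), 40–100 trials, 30–60 s
calibrations, and the architecture's stated 75 training epochs for the
high-signal benchmark (fewer for smoke tests). The high-signal benchmark —
10-fold CV on a 100-trial session at `hg_effect = 2` — reaches ~0.95 mean
accuracy in under two minutes on one CPU; null data (`hg_effect = 1`) sits
at chance. The closed-form parameter count, click-timing, voting-oracle,
bootstrap-coverage and closed-loop checks are exact or distributional and
take seconds.

## Known limitations

* The LSTM is trained full-batch-sequential in R; it is fast at the package's
  problem sizes but not intended for GPU-scale work.
* The shift-warp fit is greedy coordinate ascent; with very low SNR it can
  misplace individual trials by a frame (the suite's tolerance reflects
  this), and non-shift (affine or nonlinear) warping is out of scope.
* The speller's layout and A-DEL semantics (delete the last whole word) are
  surrogates for an interface whose exact grid is not reproduced here; both
  are configuration-driven.
* The autocomplete engine is intentionally minimal; it exists to exercise
  the suggestion interface deterministically, not to model language.
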