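# clickbci

An offline toolkit for **click-based ECoG brain-computer interfaces**: the
complete path from raw multichannel cortical recordings to a working
switch-scanning speller, built so that every stage is testable on synthetic
data with no access to patient recordings.

People with severe motor impairment can communicate through a BCI that
detects a single command — a "brain click" generated by attempting a brief
hand grasp. Attempted movement raises high-gamma (110–170 Hz) spectral power
focally over sensorimotor cortex; detecting that transient reliably, with
sub-second latency and few false alarms, is enough to drive an assistive
switch-scanning interface in which rows and columns of a key grid are
highlighted in turn and two well-timed clicks type a letter.

## The pipeline

For channel *c* and analysis window *t* (256 ms, stepped by 100 ms), the
feature is a calibration-normalized high-gamma power,

```
HG(c, t) = sum over bins f in [110, 170] Hz of
           ( log P(c, f, t) - mu_cal(c, f) ) / sd_cal(c, f)
```

with `mu_cal`, `sd_cal` the per-bin log-power statistics of a 60 s resting
calibration. Training trials (100 ms Go cue, 3–4.5 s jittered ISI) are
re-aligned by a **shift-only time warp** — one integer frame shift per trial,
shared across all channels — and frames inside the modulation window
`[onset + shift, offset + shift]` (estimated at 50% of the trial-average
peak, or pinned externally, e.g. 0.3–1.1 s post-cue) are labeled grasp.
A many-to-one **LSTM(25)–FC(10, eLU)–FC(2, softmax)** network maps 1 s of
feature history to class probabilities every 100 ms (He-normal init, Adam,
categorical cross-entropy, 45-sample batches, 75 epochs, 30% dropout;
balanced contiguous 10-fold cross-validation). A **voting window** turns the
classification stream into clicks: a click fires when grasp votes in the
last `window` classifications reach `threshold` (10-of-10 for the
communication board; 7-of-7 or 4-of-7 for the speller), followed by a 1 s
lock-out — so the minimum algorithmic latency is `threshold x 100 ms`
(400 ms at the 4-vote threshold). Performance is event-based: sensitivity
(`N_correct_clicks / N_attempted_grasps x 100%`, with a click correct iff it
lands within 1.5 s of a grasp onset), true/false-positive frequencies per
minute, latency summaries, and position-exact spelling rates (CCPM / WCPM /
CWPM), with BCa bootstrap CIs and rank-sum / Holm comparisons. Integrated
gradients attribute classifications back to channels.

The LSTM (forward, backpropagation through time, Adam, dropout) is
implemented in base R with batched matrix operations — small enough
(~15.7k parameters at 128 channels) to train in seconds-to-minutes on one
CPU.

## Worked example

Train and evaluate a full detector on synthetic study conditions (8 channels
of which 2 carry grasp modulation, in-band amplitude gain 2, 100 cued
trials):

```r
library(clickbci)

cfg    <- synth_config(n_channels = 8, hand_channels = c(3, 5),
                       hg_effect = 2, seed = 1)
calib  <- fit_calibration(generate_calibration(cfg, duration_s = 60))
sess   <- generate_training_session(cfg, n_trials = 100, seed = 2)
frames <- stream_features(sess$recording, calib)

trials <- trial_tensor(frames, sess$truth$cue_onset_ms)
warp   <- fit_shift_warp(trials, channels = select_modulated_channels(trials, 2))
onoff  <- estimate_onset_offset(warp)
labeled <- assign_labels(frames, sess$truth$cue_onset_ms,
                         shifts = warp$shift_frames,
                         cfg = label_config(onoff[1], onoff[2], c(-1, 2.5)))
folded <- balance_and_fold(labeled, k = 10, seed = 3)

cv <- cross_validate(folded, model_config(input_dim = 8, epochs = 75, seed = 4),
                     seed = 5)
glance(cv)
#> # A tibble: 1 × 5
#>   mean_accuracy sd_accuracy     k  reps pooled_accuracy
#>           <dbl>       <dbl> <int> <int>           <dbl>
#> 1         0.956      0.0193    10     1           0.956
```

Mean 10-fold CV accuracy is 0.956: the classifier cleanly separates rest
from grasp under these conditions (chance is 0.50, which is exactly where a
null session with `hg_effect = 1` lands). Now close the loop — a simulated
user spells a prompt through the switch-scanning interface with an oracle
detector — and evaluate the session log:

```r
log <- run_closed_loop(speller_layout(), scan_config(), user_config(),
                       click_detector_sim(), prompts = "the birch canoe",
                       seed = 6)
evaluate_session(log)
#> # A tibble: 9 × 3
#>   metric                          value unit
#>   <chr>                           <dbl> <chr>
#> 1 sensitivity                   100     %
#> 2 tpf                             6.95  per_min
#> 3 fpf                             0     per_min
#> 4 latency_detect_median           0.4   s
#> 5 latency_onscreen_median         0.6   s
#> 6 latency_display_offset_median   0.2   s
#> 7 ccpm                            3.26  per_min
#> 8 wcpm                            0     per_min
#> 9 cwpm                            0.652 per_min
```

Every attempted grasp produced exactly one click (sensitivity 100%, FPF 0),
detection latency is the 4-vote minimum of 0.4 s plus the 200 ms display
delay, and the 15-character prompt was typed error-free at 3.3 correct
characters per minute — two clicks per letter at the 0.67 steps/s scan rate
bounds the rate from above; higher rates require the autocomplete slots.
`autoplot()` methods exist for CV results, session performance and channel
saliency, and `tidy()`/`glance()` for fitted objects.

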