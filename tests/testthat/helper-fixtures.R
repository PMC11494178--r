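# Shared fixtures, built once per test run. All synthetic, all seeded.
# Small problem sizes: 8 channels with 2 hand channels mirrors the study's
# hand-knob fraction (12/128) at a size where an LSTM trains in seconds.

fx_cfg <- synth_config(n_channels = 8, hand_channels = c(3, 5),
                       hg_effect = 2, seed = 101)

fx_calib_rec <- generate_calibration(fx_cfg, duration_s = 30, seed = 101)
fx_calib <- fit_calibration(fx_calib_rec)

fx_session <- generate_training_session(fx_cfg, n_trials = 40, seed = 102)
fx_frames <- stream_features(fx_session$recording, fx_calib)
fx_tensor <- trial_tensor(fx_frames, fx_session$truth$cue_onset_ms)
fx_channels <- select_modulated_channels(fx_tensor, 2)
fx_warp <- fit_shift_warp(fx_tensor, channels = fx_channels)
fx_onoff <- estimate_onset_offset(fx_warp)
fx_labeled <- assign_labels(fx_frames, fx_session$truth$cue_onset_ms,
                            shifts = fx_warp$shift_frames,
                            cfg = label_config(onset_s = fx_onoff[1],
                                               offset_s = fx_onoff[2],
                                               trial_window_s = c(-1, 2.5)))
fx_folded <- balance_and_fold(fx_labeled, k = 5, seed = 103)

# One trained model shared by classifier/detector/saliency tests.
fx_model_cfg <- model_config(input_dim = 8, epochs = 25, seed = 104)
fx_model <- local({
  seqs <- make_sequences(fx_folded, fx_model_cfg$seq_len)
  use <- which(fx_folded$retained)
  use <- use[use %in% seqs$frame_row]
  sel <- match(use, seqs$frame_row)
  train_grasp_model(build_model(fx_model_cfg),
                    seqs$X[sel, , , drop = FALSE],
                    as.integer(fx_folded$label[use]))
})

# Brute-force voting-window oracle: sliding count of grasp votes over the
# last `window` classifications, click when count >= threshold and t is past
# the lock-out; on click the counter restarts (buffer cleared) and votes
# during lock-out are discarded. Written as a direct transcription of the
# rules, independent of the package's ring-buffer implementation.
oracle_votes <- function(votes, t_ms, window, threshold, lockout_ms) {
  clicks <- numeric(0)
  buf <- integer(0)
  lock_until <- -Inf
  for (i in seq_along(votes)) {
    if (t_ms[i] < lock_until) next
    buf <- c(buf, votes[i])
    if (length(buf) > window) buf <- buf[-1]
    if (sum(buf) >= threshold) {
      clicks <- c(clicks, t_ms[i])
      buf <- integer(0)
      lock_until <- t_ms[i] + lockout_ms
    }
  }
  clicks
}

# Direct Welch-style band-power oracle on a raw signal segment: mean
# periodogram power in [lo, hi] Hz over non-overlapping windows.
band_power_oracle <- function(x, fs, lo, hi, win = 256) {
  n <- floor(length(x) / win)
  stopifnot(n >= 1)
  f <- (0:(win - 1)) * fs / win
  keep <- f >= lo & f <= hi & f <= fs / 2
  p <- 0
  for (i in seq_len(n)) {
    seg <- x[((i - 1) * win + 1):(i * win)]
    p <- p + sum(abs(fft(seg))[keep]^2)
  }
  p / n
}
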