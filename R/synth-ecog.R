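#' Synthetic ECoG generator configuration
#'
#' Describes the statistical structure of the synthetic multichannel
#' recordings used to exercise the pipeline offline: a 1/f-shaped Gaussian
#' background on every channel, and on the designated "hand" channels a
#' band-limited (110-170 Hz) amplitude increase during each attempted grasp.
#' Defaults encode the study conditions of the training task: a 100 ms Go cue,
#' inter-stimulus intervals drawn uniformly from 3000-4500 ms, per-trial
#' reaction delays drawn uniformly from 150-450 ms, and an 800 ms grasp burst
#' with 50 ms cosine on/off ramps.
#'
#' @param n_channels Number of recording channels (default 128).
#' @param fs_hz Sampling rate in Hz (default 1000).
#' @param hand_channels Integer channel indices carrying grasp modulation.
#'   Defaults to the twelve hand-knob channel ids used in the study's
#'   channel-subset analysis.
#' @param hg_effect Multiplicative in-band (110-170 Hz) amplitude gain during
#'   a grasp burst; in-band *power* during the burst is `hg_effect^2` times
#'   rest power. Must be >= 1; 1 means no signal (null data).
#' @param burst_duration_ms Duration of the grasp modulation in ms.
#' @param ramp_ms Cosine on/off ramp length of the burst envelope, ms.
#' @param reaction_delay_ms Length-2 numeric, uniform bounds (ms) of the
#'   cue-to-movement-onset delay applied per trial, identically on all
#'   channels.
#' @param isi_bounds_ms Length-2 numeric, uniform bounds (ms) of the jittered
#'   inter-stimulus interval.
#' @param t_go_ms Go cue duration in ms.
#' @param lf_confound Optional low-frequency (10-30 Hz) event-related
#'   desynchronization/synchronization confound: `NULL` (off) or a list with
#'   elements `low_hz`, `high_hz`, `erd_gain` (< 1, power suppression around
#'   movement), `ers_gain` (> 1, rebound after movement). See
#'   [lf_confound_default()].
#' @param noise_exponent Spectral slope of the background: amplitude scales as
#'   `1/f^(noise_exponent/2)`, i.e. power as `1/f^noise_exponent`.
#' @param seed Integer seed; every generator drawing randomness is
#'   reproducible given the seed.
#'
#' @return An object of class `synth_config` (a named list).
#' @export
#' @examples
#' cfg <- synth_config(n_channels = 8, hand_channels = c(3, 5), seed = 1)
#' rec <- generate_calibration(cfg, duration_s = 5)
synth_config <- function(n_channels = 128,
                         fs_hz = 1000,
                         hand_channels = c(92, 93, 94, 100, 101, 102,
                                           108, 109, 110, 116, 117, 118),
                         hg_effect = 2,
                         burst_duration_ms = 800,
                         ramp_ms = 50,
                         reaction_delay_ms = c(150, 450),
                         isi_bounds_ms = c(3000, 4500),
                         t_go_ms = 100,
                         lf_confound = NULL,
                         noise_exponent = 1,
                         seed = 1) {
  stopifnot_scalar_number(n_channels, "n_channels", 1)
  stopifnot_scalar_number(fs_hz, "fs_hz", 1)
  if (fs_hz / 2 <= 170) abort("fs_hz/2 must exceed 170 Hz (the high-gamma band edge)")
  hand_channels <- sort(unique(as.integer(hand_channels)))
  if (length(hand_channels) &&
      (min(hand_channels) < 1 || max(hand_channels) > n_channels)) {
    abort("hand_channels must lie within 1..n_channels")
  }
  if (hg_effect < 1) abort("hg_effect must be >= 1 (1 = no grasp modulation)")
  if (length(isi_bounds_ms) != 2 || isi_bounds_ms[1] > isi_bounds_ms[2]) {
    abort("isi_bounds_ms must be (min, max) with min <= max")
  }
  # the minimum ISI must leave room for the burst plus labeling margins
  if (isi_bounds_ms[1] < burst_duration_ms + 1200) {
    abort("minimum ISI must be at least burst_duration_ms + 1200 ms")
  }
  if (length(reaction_delay_ms) != 2 || reaction_delay_ms[1] > reaction_delay_ms[2]) {
    abort("reaction_delay_ms must be (min, max) with min <= max")
  }
  if (!is.null(lf_confound)) {
    stopifnot(is.list(lf_confound),
              all(c("low_hz", "high_hz", "erd_gain", "ers_gain") %in% names(lf_confound)))
  }
  structure(list(
    n_channels = as.integer(n_channels), fs_hz = fs_hz,
    hand_channels = hand_channels, hg_effect = hg_effect,
    burst_duration_ms = burst_duration_ms, ramp_ms = ramp_ms,
    reaction_delay_ms = reaction_delay_ms, isi_bounds_ms = isi_bounds_ms,
    t_go_ms = t_go_ms, lf_confound = lf_confound,
    noise_exponent = noise_exponent, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default low-frequency ERD/ERS confound parameters
#'
#' Event-related desynchronization (ERD): 10-30 Hz power drops shortly before
#' and during the attempted movement; event-related synchronization (ERS):
#' power rebounds above baseline afterwards. Gains act on band amplitude, so
#' band power scales with their square.
#'
#' @param erd_gain Amplitude gain during the ERD interval (default 0.6).
#' @param ers_gain Amplitude gain during the ERS rebound (default 1.4).
#' @return A list suitable for the `lf_confound` field of [synth_config()].
#' @export
lf_confound_default <- function(erd_gain = 0.6, ers_gain = 1.4) {
  list(low_hz = 10, high_hz = 30, erd_gain = erd_gain, ers_gain = ers_gain,
       erd_window_ms = c(-300, 800), ers_window_ms = c(800, 2300))
}

#' Multichannel recording container
#'
#' A light wrapper around a samples-by-channels numeric matrix with its
#' sampling rate. Time is 0-based: sample i covers
#' `[(i-1)/fs, i/fs)` seconds.
#'
#' @param signal Numeric matrix, samples x channels.
#' @param fs_hz Sampling rate in Hz.
#' @return An object of class `ecog_recording`.
#' @export
ecog_recording <- function(signal, fs_hz) {
  signal <- as.matrix(signal)
  colnames(signal) <- channel_names(ncol(signal))
  structure(list(signal = signal, fs_hz = fs_hz), class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs_hz,
              nrow(x$signal) / x$fs_hz))
  invisible(x)
}

#' @export
as_tibble.ecog_recording <- function(x, ...) {
  out <- as_tibble(x$signal)
  dplyr::bind_cols(tibble(t_ms = (seq_len(nrow(x$signal)) - 1) * 1000 / x$fs_hz), out)
}

# 1/f^(a)-power shaped Gaussian noise, optionally restricted to a frequency
# band (band-pass mask) or with a band removed (band-stop mask). Returns an
# n x n_channels matrix; channels are independent. Shaping is exact in the
# DFT domain: unit-variance white noise is transformed, each bin scaled by
# amp(f), and inverse-transformed.
shaped_noise <- function(n, n_channels, fs_hz, exponent = 1,
                         band = NULL, stop_band = NULL) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs_hz / n          # two-sided frequency of each bin
  amp <- 1 / pmax(f, 1)^(exponent / 2)
  amp[1] <- 0                               # no DC drift
  if (!is.null(band)) amp[f < band[1] | f > band[2]] <- 0
  if (!is.null(stop_band)) amp[f >= stop_band[1] & f <= stop_band[2]] <- 0
  out <- matrix(0, n, n_channels)
  for (ch in seq_len(n_channels)) {
    x <- rnorm(n)
    out[, ch] <- Re(fft(fft(x) * amp, inverse = TRUE)) / n
  }
  out
}

# Burst envelope over n samples: for each onset (ms), raise a plateau of
# `dur_ms` with cosine ramps of `ramp_ms` at both ends. Values in [0, 1].
burst_envelope <- function(n, fs_hz, onsets_ms, dur_ms, ramp_ms) {
  env <- numeric(n)
  n_dur <- round(dur_ms * fs_hz / 1000)
  n_ramp <- round(ramp_ms * fs_hz / 1000)
  shape <- c(0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp)),
             rep(1, max(n_dur - 2 * n_ramp, 0)),
             0.5 * (1 + cos(pi * seq_len(n_ramp) / n_ramp)))
  for (m in onsets_ms) {
    i0 <- round(m * fs_hz / 1000) + 1
    idx <- i0:(i0 + length(shape) - 1)
    ok <- idx >= 1 & idx <= n
    env[idx[ok]] <- pmax(env[idx[ok]], shape[ok])
  }
  env
}

# Piecewise gain profile for the low-frequency confound.
lf_gain_profile <- function(n, fs_hz, onsets_ms, lf) {
  g <- rep(1, n)
  for (m in onsets_ms) {
    erd <- round((m + lf$erd_window_ms) * fs_hz / 1000) + 1
    ers <- round((m + lf$ers_window_ms) * fs_hz / 1000) + 1
    erd <- pmax(pmin(erd, n), 1); ers <- pmax(pmin(ers, n), 1)
    g[erd[1]:erd[2]] <- lf$erd_gain
    g[ers[1]:ers[2]] <- lf$ers_gain
  }
  g
}

# Core signal synthesis shared by calibration and training sessions.
# movement_onsets_ms may be empty (pure rest).
synthesize_signal <- function(cfg, n_samples, movement_onsets_ms = numeric(0)) {
  lf <- cfg$lf_confound
  if (is.null(lf)) {
    sig <- shaped_noise(n_samples, cfg$n_channels, cfg$fs_hz, cfg$noise_exponent)
  } else {
    # split the background at the confound band so its gain can be modulated
    base <- shaped_noise(n_samples, cfg$n_channels, cfg$fs_hz, cfg$noise_exponent,
                         stop_band = c(lf$low_hz, lf$high_hz))
    lfno <- shaped_noise(n_samples, cfg$n_channels, cfg$fs_hz, cfg$noise_exponent,
                         band = c(lf$low_hz, lf$high_hz))
    g <- lf_gain_profile(n_samples, cfg$fs_hz, movement_onsets_ms, lf)
    sig <- base + lfno * g
  }
  if (length(movement_onsets_ms) && cfg$hg_effect > 1 && length(cfg$hand_channels)) {
    env <- burst_envelope(n_samples, cfg$fs_hz, movement_onsets_ms,
                          cfg$burst_duration_ms, cfg$ramp_ms)
    scale <- sqrt(cfg$hg_effect^2 - 1)
    hg <- shaped_noise(n_samples, length(cfg$hand_channels), cfg$fs_hz,
                       cfg$noise_exponent, band = c(110, 170))
    sig[, cfg$hand_channels] <- sig[, cfg$hand_channels] + hg * (env * scale)
  }
  ecog_recording(sig, cfg$fs_hz)
}

#' Generate a resting-state calibration recording
#'
#' Stationary rest-state noise with no grasp modulation, used to fit the
#' per-channel, per-frequency-bin normalization statistics. The study
#' convention is a 60 s calibration block at the start of each session.
#'
#' @param cfg A [synth_config()].
#' @param duration_s Duration in seconds (>= 1).
#' @param seed Optional seed overriding `cfg$seed`.
#' @return An [ecog_recording()].
#' @export
generate_calibration <- function(cfg, duration_s = 60, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  stopifnot_scalar_number(duration_s, "duration_s", 1)
  n <- round(duration_s * cfg$fs_hz)
  with_seed(seed, synthesize_signal(cfg, n))
}

#' Generate a cued training session with ground truth
#'
#' Emulates the training task: each trial is a 100 ms Go cue followed by a
#' uniformly jittered inter-stimulus interval; the attempted grasp begins a
#' per-trial uniform reaction delay after the cue and modulates in-band
#' (110-170 Hz) amplitude on the hand channels for `burst_duration_ms`.
#' The same delay applies to all channels, so trials are exactly realignable
#' by a per-trial time shift.
#'
#' @param cfg A [synth_config()].
#' @param n_trials Number of cued trials (>= 1).
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A list with elements `recording` (an [ecog_recording()]) and
#'   `truth` (a tibble: `trial`, `cue_onset_ms`, `delay_ms`,
#'   `movement_onset_ms`).
#' @export
generate_training_session <- function(cfg, n_trials, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  stopifnot_scalar_number(n_trials, "n_trials", 1)
  with_seed(seed, {
    isi <- runif(n_trials, cfg$isi_bounds_ms[1], cfg$isi_bounds_ms[2])
    delay <- runif(n_trials, cfg$reaction_delay_ms[1], cfg$reaction_delay_ms[2])
    cues <- 2000 + cumsum(c(0, head(cfg$t_go_ms + isi, -1)))
    onsets <- cues + delay
    n <- round((max(onsets) + 3600) * cfg$fs_hz / 1000)
    rec <- synthesize_signal(cfg, n, movement_onsets_ms = onsets)
    list(recording = rec,
         truth = tibble(trial = seq_len(n_trials),
                        cue_onset_ms = cues,
                        delay_ms = delay,
                        movement_onset_ms = onsets))
  })
}

#' Generate a free-running session with grasp bursts at given times
#'
#' Synthesizes a continuous recording whose grasp bursts occur at supplied
#' movement-onset times (for example the intent times logged by a simulated
#' spelling session), so the full offline pipeline can be run against it.
#'
#' @param cfg A [synth_config()].
#' @param movement_onsets_ms Numeric vector of burst onset times (ms).
#' @param duration_ms Total recording length (ms); defaults to the last onset
#'   plus 3.6 s.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return An [ecog_recording()].
#' @export
generate_session_from_onsets <- function(cfg, movement_onsets_ms,
                                         duration_ms = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(duration_ms)) duration_ms <- max(movement_onsets_ms, 0) + 3600
  n <- round(duration_ms * cfg$fs_hz / 1000)
  with_seed(seed, synthesize_signal(cfg, n, movement_onsets_ms = movement_onsets_ms))
}
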