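#' Spectral feature extraction configuration
#'
#' Raw signal is converted into features by estimating spectral power over
#' 256 ms windows advanced in 100 ms steps, log-transforming each frequency
#' bin, z-scoring each bin against resting calibration statistics, and summing
#' the z-scores of the bins whose center frequency lies in the high-gamma band
#' (110-170 Hz inclusive). The same arithmetic is used for training data and
#' streaming inference.
#'
#' A frame's timestamp is the trailing (right) edge of its window: the moment
#' the feature becomes available, matching the convention that a sequence is
#' labeled at its leading edge.
#'
#' @param fs_hz Sampling rate, Hz.
#' @param window_ms Analysis window length, ms; `window_ms * fs_hz / 1000`
#'   must be a whole number of samples.
#' @param step_ms Hop between successive windows, ms.
#' @param hg_low_hz,hg_high_hz High-gamma band edges, Hz; a bin belongs to the
#'   band iff its center frequency f satisfies `hg_low_hz <= f <= hg_high_hz`.
#' @param taper `"hann"` (default) or `"rectangular"` window applied before
#'   the transform.
#' @param normalization `"z_then_sum"` (default): z-score each in-band bin
#'   then sum; or `"sum_then_z"`: sum raw in-band log-powers then z-score the
#'   sum against calibration statistics of the same sum.
#' @param sd_floor Minimum allowed calibration standard deviation; degenerate
#'   (constant) channels are floored here with a warning.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(fs_hz = 1000, window_ms = 256, step_ms = 100,
                            hg_low_hz = 110, hg_high_hz = 170,
                            taper = c("hann", "rectangular"),
                            normalization = c("z_then_sum", "sum_then_z"),
                            sd_floor = 1e-6) {
  taper <- match.arg(taper)
  normalization <- match.arg(normalization)
  n_win <- window_ms * fs_hz / 1000
  if (abs(n_win - round(n_win)) > 1e-9) {
    abort("window_ms * fs_hz / 1000 must be an integer sample count")
  }
  if (hg_high_hz >= fs_hz / 2) abort("hg_high_hz must be below Nyquist")
  if (hg_low_hz >= hg_high_hz) abort("hg_low_hz must be below hg_high_hz")
  structure(list(fs_hz = fs_hz, window_ms = window_ms, step_ms = step_ms,
                 hg_low_hz = hg_low_hz, hg_high_hz = hg_high_hz,
                 taper = taper, normalization = normalization,
                 sd_floor = sd_floor,
                 n_window = as.integer(round(n_win)),
                 n_step = as.integer(round(step_ms * fs_hz / 1000))),
            class = "spectral_config")
}

# One-sided bin center frequencies for the configured window.
bin_frequencies <- function(cfg) {
  (0:(cfg$n_window %/% 2)) * cfg$fs_hz / cfg$n_window
}

# Indices (into the one-sided spectrum) of in-band bins, inclusive band edges.
hg_band_bins <- function(cfg) {
  f <- bin_frequencies(cfg)
  which(f >= cfg$hg_low_hz & f <= cfg$hg_high_hz)
}

taper_vector <- function(cfg) {
  n <- cfg$n_window
  if (cfg$taper == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n) else rep(1, n)
}

#' Per-bin log spectral power of one analysis window
#'
#' Computes the one-sided power spectrum of a single window of multichannel
#' samples (taper, FFT, power-spectral-density scaling) and returns the
#' natural log of each bin's power. Deterministic.
#'
#' @param segment Numeric matrix, exactly `window_ms` worth of samples by
#'   channels (vector accepted for one channel).
#' @param cfg A [spectral_config()].
#' @return Numeric matrix, channels x frequency bins. Column names are bin
#'   center frequencies in Hz.
#' @export
#' @examples
#' cfg <- spectral_config()
#' seg <- matrix(sin(2 * pi * 125 * (0:255) / 1000), ncol = 1)
#' lp <- frame_logpower(seg, cfg)
frame_logpower <- function(segment, cfg) {
  segment <- as.matrix(segment)
  if (nrow(segment) != cfg$n_window) {
    abort(sprintf("segment must have exactly %d samples, got %d",
                  cfg$n_window, nrow(segment)))
  }
  if (!all(is.finite(segment))) abort("segment contains non-finite values")
  w <- taper_vector(cfg)
  n <- cfg$n_window
  X <- stats::mvfft(segment * w)
  half <- seq_len(n %/% 2 + 1)
  p <- abs(X[half, , drop = FALSE])^2 / (cfg$fs_hz * sum(w^2))
  # one-sided: double everything except DC and Nyquist
  dbl <- rep(2, length(half)); dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(half)] <- 1
  p <- p * dbl
  out <- t(log(pmax(p, .Machine$double.xmin)))
  colnames(out) <- sprintf("%.6g", bin_frequencies(cfg))
  out
}

# Start sample indices (1-based) of every full window in a signal of length n.
window_starts <- function(n, cfg) {
  if (n < cfg$n_window) abort("signal shorter than one analysis window")
  seq(1L, n - cfg$n_window + 1L, by = cfg$n_step)
}

#' Fit resting calibration statistics
#'
#' Computes the per-channel, per-frequency-bin mean and standard deviation of
#' log spectral power across all frames of a rest recording at the standard
#' 100 ms cadence. These statistics normalize power estimates during both
#' model training and online operation.
#'
#' @param recording An [ecog_recording()] of rest data (>= one window).
#' @param cfg A [spectral_config()].
#' @return An object of class `bci_calibration`: list with `mean` and `sd`
#'   (channels x bins matrices, sd floored at `cfg$sd_floor`), `band_mean` and
#'   `band_sd` (per-channel statistics of the summed in-band log-power, used
#'   by the `"sum_then_z"` normalization), `n_frames`, and `cfg`.
#' @export
fit_calibration <- function(recording, cfg = spectral_config()) {
  stopifnot(inherits(recording, "ecog_recording"))
  sig <- recording$signal
  starts <- window_starts(nrow(sig), cfg)
  n_ch <- ncol(sig)
  bins <- length(bin_frequencies(cfg))
  band <- hg_band_bins(cfg)
  s1 <- matrix(0, n_ch, bins); s2 <- matrix(0, n_ch, bins)
  b1 <- numeric(n_ch); b2 <- numeric(n_ch)
  for (s in starts) {
    lp <- frame_logpower(sig[s:(s + cfg$n_window - 1), , drop = FALSE], cfg)
    s1 <- s1 + lp; s2 <- s2 + lp^2
    bs <- rowSums(lp[, band, drop = FALSE])
    b1 <- b1 + bs; b2 <- b2 + bs^2
  }
  nf <- length(starts)
  mu <- s1 / nf
  va <- pmax(s2 / nf - mu^2, 0) * nf / max(nf - 1, 1)
  sdv <- sqrt(va)
  if (any(sdv < cfg$sd_floor)) {
    warn("some calibration bins had near-zero variance; sd floored")
  }
  sdv <- pmax(sdv, cfg$sd_floor)
  bmu <- b1 / nf
  bsd <- pmax(sqrt(pmax(b2 / nf - bmu^2, 0) * nf / max(nf - 1, 1)), cfg$sd_floor)
  structure(list(mean = mu, sd = sdv, band_mean = bmu, band_sd = bsd,
                 n_frames = nf, cfg = cfg),
            class = "bci_calibration")
}

#' @export
print.bci_calibration <- function(x, ...) {
  cat(sprintf("<bci_calibration> %d channels x %d bins from %d frames\n",
              nrow(x$mean), ncol(x$mean), x$n_frames))
  invisible(x)
}

#' Calibration-normalized high-gamma value of one log-power frame
#'
#' Under the default `"z_then_sum"` normalization, each in-band bin's
#' log-power is z-scored against calibration and the z-scores are summed per
#' channel. Under `"sum_then_z"` the raw in-band log-powers are summed first
#' and the sum is z-scored.
#'
#' @param logpower Channels x bins matrix from [frame_logpower()].
#' @param calib A [fit_calibration()] result.
#' @return Numeric vector, one high-gamma value per channel.
#' @export
hg_feature <- function(logpower, calib) {
  cfg <- calib$cfg
  if (!all(dim(logpower) == dim(calib$mean))) {
    abort("logpower shape does not match calibration statistics")
  }
  band <- hg_band_bins(cfg)
  if (cfg$normalization == "z_then_sum") {
    z <- (logpower[, band, drop = FALSE] - calib$mean[, band, drop = FALSE]) /
      calib$sd[, band, drop = FALSE]
    unname(rowSums(z))
  } else {
    unname((rowSums(logpower[, band, drop = FALSE]) - calib$band_mean) /
             calib$band_sd)
  }
}

#' Extract the high-gamma feature stream of a recording
#'
#' One feature frame per 100 ms step, the first frame emitted when the running
#' buffer first fills (timestamp = window length). Output is identical whether
#' the signal is processed whole or delivered in packets (see
#' [packetized_features()]).
#'
#' @param recording An [ecog_recording()] (or samples x channels matrix).
#' @param calib A [fit_calibration()] result.
#' @return A tibble: `t_ms` (window trailing edge, ms from recording start)
#'   plus one `ch###` column per channel.
#' @export
stream_features <- function(recording, calib) {
  sig <- if (inherits(recording, "ecog_recording")) recording$signal else as.matrix(recording)
  cfg <- calib$cfg
  starts <- window_starts(nrow(sig), cfg)
  hg <- matrix(NA_real_, length(starts), ncol(sig))
  for (i in seq_along(starts)) {
    s <- starts[i]
    lp <- frame_logpower(sig[s:(s + cfg$n_window - 1), , drop = FALSE], cfg)
    hg[i, ] <- hg_feature(lp, calib)
  }
  t_ms <- (starts - 1 + cfg$n_window) * 1000 / cfg$fs_hz
  feature_tibble(t_ms, hg)
}

#' Packetized (streaming) feature extraction
#'
#' Processes the signal in packets of `packet_ms`, maintaining a running
#' window buffer exactly as an online system would, and emits a feature frame
#' whenever a full window at the 100 ms cadence becomes available. The result
#' is bit-identical to [stream_features()] on the whole signal.
#'
#' @inheritParams stream_features
#' @param packet_ms Packet size in ms (default 100).
#' @return Same as [stream_features()].
#' @export
packetized_features <- function(recording, calib, packet_ms = 100) {
  sig <- if (inherits(recording, "ecog_recording")) recording$signal else as.matrix(recording)
  cfg <- calib$cfg
  n_pkt <- max(1L, as.integer(round(packet_ms * cfg$fs_hz / 1000)))
  buf <- matrix(numeric(0), 0, ncol(sig))
  n_seen <- 0L
  next_start <- 1L                # absolute start index of the next frame
  rows <- list(); ts <- numeric(0)
  pos <- 1L
  while (pos <= nrow(sig)) {
    pkt <- sig[pos:min(pos + n_pkt - 1L, nrow(sig)), , drop = FALSE]
    pos <- pos + nrow(pkt)
    buf <- rbind(buf, pkt)
    n_seen <- n_seen + nrow(pkt)
    while (next_start + cfg$n_window - 1L <= n_seen) {
      off <- next_start - (n_seen - nrow(buf))   # index within buffer
      seg <- buf[off:(off + cfg$n_window - 1L), , drop = FALSE]
      lp <- frame_logpower(seg, cfg)
      rows[[length(rows) + 1L]] <- hg_feature(lp, calib)
      ts <- c(ts, (next_start - 1L + cfg$n_window) * 1000 / cfg$fs_hz)
      next_start <- next_start + cfg$n_step
    }
    drop <- next_start - (n_seen - nrow(buf)) - 1L
    if (drop > 0) buf <- buf[-seq_len(min(drop, nrow(buf))), , drop = FALSE]
  }
  if (length(rows) == 0) abort("signal shorter than one analysis window")
  feature_tibble(ts, do.call(rbind, rows))
}
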