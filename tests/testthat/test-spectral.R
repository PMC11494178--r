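cfg_sp <- spectral_config()

test_that("a bin-centered sinusoid dominates its own frequency bin", {
  f0 <- 125                                   # 125 Hz = bin 32 of 256 @ 1 kHz
  x <- sin(2 * pi * f0 * (0:255) / 1000)
  lp <- frame_logpower(matrix(x, ncol = 1), cfg_sp)
  freqs <- as.numeric(colnames(lp))
  # direct DFT oracle: rectangular-window periodogram peaks at the same bin
  oracle_bin <- which.max(abs(fft(x))[1:129])
  expect_equal(unname(which.max(lp[1, ])), oracle_bin)
  expect_equal(freqs[which.max(lp[1, ])], f0)
  # dominance over every other bin
  expect_true(all(lp[1, which.max(lp[1, ])] > lp[1, -which.max(lp[1, ])]))
})

test_that("log-power is deterministic and scales as amplitude squared", {
  x <- sin(2 * pi * 125 * (0:255) / 1000) + 0.01 * cos(2 * pi * 50 * (0:255) / 1000)
  seg <- cbind(x, x)
  lp <- frame_logpower(seg, cfg_sp)
  expect_identical(lp[1, ], lp[2, ])          # identical channels, identical rows
  lp2 <- frame_logpower(seg * 2, cfg_sp)
  k <- which.max(lp[1, ])
  expect_equal(lp2[1, k] - lp[1, k], log(4), tolerance = 1e-9)
})

test_that("frame_logpower validates its input", {
  expect_error(frame_logpower(matrix(0, 100, 1), cfg_sp), "256")
  expect_error(frame_logpower(matrix(NA_real_, 256, 1), cfg_sp), "finite")
})

test_that("calibration self-normalization gives per-bin mean 0 and sd 1", {
  cfg <- synth_config(n_channels = 2, hand_channels = 1, seed = 3)
  rec <- generate_calibration(cfg, 60)
  calib <- fit_calibration(rec)
  expect_equal(calib$n_frames, 598)           # floor((60000-256)/100)+1
  # z-score every calibration frame against its own stats
  zsum <- matrix(0, 2, ncol(calib$mean)); z2sum <- zsum
  starts <- seq(1, 60000 - 256 + 1, by = 100)
  for (s in starts) {
    lp <- frame_logpower(rec$signal[s:(s + 255), ], calib$cfg)
    z <- (lp - calib$mean) / calib$sd
    zsum <- zsum + z; z2sum <- z2sum + z^2
  }
  mu <- zsum / length(starts)
  sdv <- sqrt((z2sum / length(starts) - mu^2) * length(starts) / (length(starts) - 1))
  expect_lt(max(abs(mu)), 0.05)
  expect_lt(max(abs(sdv - 1)), 0.05)
})

test_that("identical channels get identical calibration statistics", {
  sig <- matrix(rnorm(5000), ncol = 1)
  rec <- ecog_recording(cbind(sig, sig), 1000)
  calib <- fit_calibration(rec)
  expect_identical(calib$mean[1, ], calib$mean[2, ])
  expect_identical(calib$sd[1, ], calib$sd[2, ])
})

test_that("degenerate constant channels are floored with a warning", {
  rec <- ecog_recording(cbind(rnorm(2000), rep(1, 2000)), 1000)
  expect_warning(calib <- fit_calibration(rec), "floored")
  expect_true(all(calib$sd >= calib$cfg$sd_floor))
})

test_that("hg_feature implements the sum-of-z definition", {
  calib <- fx_calib
  band <- clickbci:::hg_band_bins(calib$cfg)
  # log-power equal to the calibration mean everywhere -> all-zero vector
  expect_equal(hg_feature(calib$mean, calib), rep(0, nrow(calib$mean)))
  # one in-band bin at mean + 2 sd -> that channel reads exactly 2
  lp <- calib$mean
  lp[1, band[3]] <- lp[1, band[3]] + 2 * calib$sd[1, band[3]]
  v <- hg_feature(lp, calib)
  expect_equal(v[1], 2)
  expect_equal(v[-1], rep(0, nrow(lp) - 1))
  # perturbing a bin below the band leaves the value unchanged
  freqs <- clickbci:::bin_frequencies(calib$cfg)
  low_bin <- max(which(freqs < 110))
  lp2 <- calib$mean
  lp2[1, low_bin] <- lp2[1, low_bin] + 5
  expect_equal(hg_feature(lp2, calib), rep(0, nrow(lp2)))
  expect_error(hg_feature(calib$mean[, 1:10], calib), "shape")
})

test_that("the high-gamma band is inclusive of both edges", {
  # with a 500-sample window at 1 kHz, bins fall exactly on 110 and 170 Hz
  cfg <- spectral_config(window_ms = 500)
  f <- clickbci:::bin_frequencies(cfg)
  bins <- clickbci:::hg_band_bins(cfg)
  expect_true(110 %in% f[bins])
  expect_true(170 %in% f[bins])
  expect_false(any(f[bins] < 110 | f[bins] > 170))
})

test_that("frame count follows floor((N - 256)/100) + 1 and timestamps step by 100 ms", {
  calib <- fx_calib
  for (n_ms in c(256, 300, 1000, 2560, 4321)) {
    fr <- stream_features(fx_calib_rec$signal[1:n_ms, ], calib)
    expect_equal(nrow(fr), floor((n_ms - 256) / 100) + 1)
    expect_equal(fr$t_ms[1], 256)
    if (nrow(fr) > 1) expect_equal(unique(diff(fr$t_ms)), 100)
  }
  expect_error(stream_features(fx_calib_rec$signal[1:200, ], calib), "window")
})

test_that("whole-signal and packetized processing agree bit for bit", {
  sig <- fx_session$recording$signal[1:3000, ]
  whole <- stream_features(sig, fx_calib)
  for (pkt in c(100, 73, 256, 1000)) {
    expect_identical(packetized_features(sig, fx_calib, packet_ms = pkt), whole)
  }
})

test_that("the sum-then-z normalization alternative is available and self-consistent", {
  cfg <- spectral_config(normalization = "sum_then_z")
  rec <- ecog_recording(fx_calib_rec$signal[1:10000, ], 1000)
  calib <- fit_calibration(rec, cfg)
  fr <- stream_features(rec, calib)
  m <- clickbci:::feature_matrix(fr)
  # self-normalization: per-channel mean ~ 0, sd ~ 1
  expect_lt(max(abs(colMeans(m))), 0.1)
  expect_lt(max(abs(apply(m, 2, sd) - 1)), 0.1)
})
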