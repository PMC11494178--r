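# Helper: build a feature tibble on the exact 100 ms grid with planted
# channel traces (frames x channels matrix).
grid_frames <- function(mat, t0 = 0) {
  clickbci:::feature_tibble(t0 + (seq_len(nrow(mat)) - 1) * 100, mat)
}

test_that("select_modulated_channels finds planted channels and breaks ties low", {
  set.seed(42)
  n_tr <- 8; n_f <- 36; n_ch <- 6
  tens <- array(rnorm(n_tr * n_f * n_ch, sd = 0.1), c(n_tr, n_f, n_ch))
  post <- 15:22                              # ~0.4-1.1 s post cue
  tens[, post, 5] <- tens[, post, 5] + 3
  tens[, post, 2] <- tens[, post, 2] + 2
  trials <- list(tensor = tens, rel_t_ms = seq(-1000, 2500, by = 100))
  expect_equal(select_modulated_channels(trials, 2), c(2, 5))
  # all channels identical -> lowest indices win
  flat <- list(tensor = array(1, c(n_tr, n_f, n_ch)),
               rel_t_ms = seq(-1000, 2500, by = 100))
  expect_equal(select_modulated_channels(flat, 3), 1:3)
  expect_error(select_modulated_channels(flat, 10), "channel count")
})

test_that("fit_shift_warp recovers planted integer shifts up to a global constant", {
  base <- matrix(0, 36, 2)
  base[15:22, 1] <- 5; base[15:22, 2] <- 4    # boxcar modulation
  planted <- c(0L, 2L, -1L, 1L, 0L)
  tens <- array(0, c(5, 36, 2))
  for (j in 1:5) {
    tens[j, , ] <- clickbci:::shift_trace(base, -planted[j]) # delay by planted
    tens[j, , ][is.na(tens[j, , ])] <- 0
  }
  tens <- tens + array(rnorm(length(tens), sd = 0.05), dim(tens))
  trials <- list(tensor = tens, rel_t_ms = seq(-1000, 2500, by = 100))
  w <- fit_shift_warp(trials, max_shift_frames = 3)
  rec <- w$shift_frames - w$shift_frames[1]
  expect_equal(rec, planted - planted[1])
  # identical trials -> all shifts zero
  same <- array(rep(base, each = 4), c(4, 36, 2))
  w0 <- fit_shift_warp(list(tensor = same, rel_t_ms = trials$rel_t_ms))
  expect_equal(w0$shift_frames, rep(0L, 4))
  expect_true(w0$converged)
})

test_that("alignment does not decrease mean pairwise inter-trial correlation", {
  sub <- fx_tensor$tensor[, , fx_channels, drop = FALSE]
  pair_cor <- function(tens, shifts) {
    n <- dim(tens)[1]; tot <- 0; cnt <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      ta <- clickbci:::shift_trace(matrix(tens[a, , ], dim(tens)[2]), shifts[a])
      tb <- clickbci:::shift_trace(matrix(tens[b, , ], dim(tens)[2]), shifts[b])
      ok <- stats::complete.cases(ta) & stats::complete.cases(tb)
      tot <- tot + stats::cor(as.numeric(ta[ok, ]), as.numeric(tb[ok, ]))
      cnt <- cnt + 1
    }
    tot / cnt
  }
  before <- pair_cor(sub, rep(0L, dim(sub)[1]))
  after <- pair_cor(sub, fx_warp$shift_frames)
  expect_gte(after, before)
})

test_that("shift recovery matches planted reaction delays on synthetic sessions", {
  # the generator applies one delay per trial across all channels, so the
  # recovered shifts must track the planted delays up to a global constant
  # shifts are integer while the planted delays are continuous, so recovery
  # is assessed up to the best global constant (Chebyshev center of the
  # residuals) with a one-frame tolerance on top of the +-0.5 quantization
  planted_frames <- fx_session$truth$delay_ms / 100
  d <- fx_warp$shift_frames - planted_frames
  resid <- d - (max(d) + min(d)) / 2
  expect_lte(max(abs(resid)), 1.5)
})

test_that("estimate_onset_offset finds a boxcar and honors overrides", {
  rel <- seq(-1000, 2500, by = 100)
  template <- matrix(0, length(rel), 1)
  template[rel >= 250 & rel <= 1050, 1] <- 2   # elevation 0.25-1.05 s
  w <- structure(list(template = template, rel_t_ms = rel), class = "shift_warp")
  oo <- estimate_onset_offset(w, threshold_fraction = 0.5)
  expect_lte(abs(oo["onset_s"] - 0.25), 0.1)   # within one frame
  expect_lte(abs(oo["offset_s"] - 1.05), 0.1)
  # the study's values pass through an override verbatim
  expect_equal(unname(estimate_onset_offset(w, override = c(0.3, 1.1))),
               c(0.3, 1.1))
  flat <- structure(list(template = matrix(0, length(rel), 1), rel_t_ms = rel),
                    class = "shift_warp")
  expect_error(estimate_onset_offset(flat), "flat")
})

test_that("assign_labels applies the closed interval onset..offset plus shift", {
  mat <- matrix(0, 120, 1)
  fr <- grid_frames(mat)                      # frames at 0, 100, ..., 11900
  lab <- assign_labels(fr, cue_onsets_ms = 5000, shifts = 0L)
  grasp_t <- lab$t_ms[lab$label == "grasp"]
  # closed 800 ms interval on the 100 ms grid: 5300..6100, 9 frames
  expect_equal(grasp_t, seq(5300, 6100, by = 100))
  expect_equal(length(grasp_t), 9)
  # grasp-labeled time span per trial equals offset - onset = 800 ms
  expect_equal(max(grasp_t) - min(grasp_t), 800)
  # a +2 frame shift translates the window by exactly 200 ms
  lab2 <- assign_labels(fr, cue_onsets_ms = 5000, shifts = 2L)
  expect_equal(lab$t_ms[lab$label == "grasp"] + 200,
               lab2$t_ms[lab2$label == "grasp"])
  expect_equal(unique(lab$trial_id[lab$label == "grasp"]), 1L)
  expect_true(all(is.na(lab$trial_id[lab$label == "rest"])))
})

test_that("assign_labels rejects overlapping grasp windows and shift mismatch", {
  fr <- grid_frames(matrix(0, 60, 1))
  expect_error(assign_labels(fr, c(1000, 1400)), "overlap")
  expect_error(assign_labels(fr, c(1000, 5000), shifts = 0L), "one shift per trial")
})

test_that("balance_and_fold yields contiguous class-balanced folds", {
  fo <- fx_folded
  k <- max(fo$fold)
  for (f in seq_len(k)) {
    kept <- fo[fo$retained & fo$fold == f, ]
    # equal class sizes within every fold
    expect_equal(sum(kept$label == "rest"), sum(kept$label == "grasp"))
    # contiguity: every fold occupies a single time interval
    rng <- range(fo$t_ms[fo$fold == f])
    expect_true(all(fo$fold[fo$t_ms >= rng[1] & fo$t_ms <= rng[2]] == f))
  }
  # folds partition all frames; downsampling removed only rest frames
  expect_equal(sort(unique(fo$fold)), 1:k)
  expect_true(all(fo$label[!fo$retained] == "rest"))
  # near-equal grasp counts across folds
  g <- table(fo$fold[fo$label == "grasp"])
  expect_lte(diff(range(g)), 1)
  # seeded determinism
  again <- balance_and_fold(fx_labeled, k = 5, seed = 103)
  expect_identical(fo$retained, again$retained)
  expect_error(balance_and_fold(fx_labeled, k = 1e6), "fewer grasp samples")
})
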