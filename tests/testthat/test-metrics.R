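mk_clicks <- function(onscreen, detect = onscreen - 200) {
  tibble::tibble(detect_t_ms = detect, onscreen_t_ms = onscreen)
}

test_that("the 1.5 s true-positive window is inclusive and one click matches one grasp", {
  # click 1.4 s after onset: TP
  al <- align_events(1000, mk_clicks(2400), duration_min = 1)
  expect_equal(c(al$n_tp, al$n_fp, al$n_fn), c(1, 0, 0))
  # click exactly at the boundary: TP (inclusive)
  al <- align_events(1000, mk_clicks(2500), duration_min = 1)
  expect_equal(al$n_tp, 1)
  # click 1.6 s after the only onset: 1 FP and 1 FN
  al <- align_events(1000, mk_clicks(2600), duration_min = 1)
  expect_equal(c(al$n_tp, al$n_fp, al$n_fn), c(0, 1, 1))
  # zero grasps, three clicks: 3 FP
  al <- align_events(numeric(0), mk_clicks(c(100, 200, 300)), duration_min = 1)
  expect_equal(al$n_fp, 3)
  # greedy earliest-first: two clicks inside one window, first matches
  al <- align_events(1000, mk_clicks(c(1500, 2000)), duration_min = 1)
  expect_equal(al$matches$onscreen_t_ms, 1500)
  expect_equal(al$n_fp, 1)
  expect_error(align_events(c(2000, 1000), mk_clicks(100), duration_min = 1),
               "sorted")
})

test_that("alignment conserves counts against a brute-force counting oracle", {
  set.seed(5)
  for (i in 1:20) {
    onsets <- sort(runif(sample(0:12, 1), 0, 60000))
    clicks <- sort(runif(sample(0:12, 1), 0, 60000))
    al <- align_events(onsets, mk_clicks(clicks), duration_min = 1)
    expect_equal(al$n_tp + al$n_fn, length(onsets))      # grasps partition
    expect_equal(al$n_tp + al$n_fp, length(clicks))      # clicks partition
    expect_equal(al$n_tp, nrow(al$matches))
    # no click matched twice, all matches inside the window
    expect_false(any(duplicated(al$matches$onscreen_t_ms)))
    lat <- al$matches$onscreen_t_ms - al$matches$grasp_onset_ms
    expect_true(all(lat >= 0 & lat <= 1500))
  }
})

test_that("sensitivity and rates implement their defining ratios", {
  onsets <- seq(1000, by = 3000, length.out = 10)
  clicks <- mk_clicks(onsets[1:9] + 500)                 # 9 TP of 10
  al <- align_events(onsets, clicks, duration_min = 10)
  expect_equal(click_sensitivity(al), 90)
  r <- click_rates(al)
  expect_equal(r$tpf_per_min, 0.9)
  expect_equal(r$fpf_per_min, 0)
  # all matched -> 100, none matched -> 0
  expect_equal(click_sensitivity(align_events(1000, mk_clicks(1500),
                                              duration_min = 1)), 100)
  expect_equal(click_sensitivity(align_events(1000, mk_clicks(numeric(0)),
                                              duration_min = 1)), 0)
  # FPF arithmetic and per-hour conversion: 0.029/min = 1.74/h
  al2 <- align_events(numeric(0), mk_clicks(c(1000, 2000)), duration_min = 10)
  expect_equal(click_rates(al2)$fpf_per_min, 0.2)
  al3 <- align_events(numeric(0), mk_clicks(1000), duration_min = 1 / 0.029)
  expect_equal(click_rates(al3)$fpf_per_h, 1.74)
  expect_error(click_sensitivity(align_events(numeric(0), mk_clicks(1),
                                              duration_min = 1)), "undefined")
  expect_error(click_rates(align_events(1, mk_clicks(1), duration_min = 0)),
               "positive")
})

test_that("latency summaries report both kinds and the constant display offset", {
  onsets <- c(1000, 5000, 9000)
  clicks <- mk_clicks(onsets + c(600, 700, 800))
  al <- align_events(onsets, clicks, duration_min = 1)
  ls <- latency_stats(al)
  off <- ls[ls$latency == "display_offset", ]
  expect_equal(off$median_ms, 200)
  expect_equal(off$mean_ms, 200)
  det <- ls[ls$latency == "detect", ]
  expect_equal(det$median_ms, 500)
  # single TP: median = mean = that latency
  al1 <- align_events(1000, mk_clicks(1700), duration_min = 1)
  l1 <- latency_stats(al1)
  expect_equal(l1$median_ms[l1$latency == "onscreen"], 700)
  expect_equal(l1$mean_ms[l1$latency == "onscreen"], 700)
  expect_error(latency_stats(align_events(1000, mk_clicks(numeric(0)),
                                          duration_min = 1)), "no true positives")
})

test_that("spelling rates use position-exact matching", {
  # 30 characters, 5 words, one character typo in the final output:
  # 29 correct characters and 4 correct words
  prompt <- "abcde fghij klmno pqrst uvwxy"   # 29 chars + spaces = 5 words
  stopifnot(nchar(prompt) == 29)
  typed <- "abcde fghij klmnX pqrst uvwxy"
  sp <- spelling_rates(paste0(prompt, "z"), paste0(typed, "z"), duration_min = 1)
  expect_equal(sp$n_correct_chars, 29)
  expect_equal(sp$n_correct_words, 4)
  # perfect 20-char transcription in 2 min: CCPM 10, WCPM 0
  p20 <- "abcdefghij klmnopqrs"
  sp2 <- spelling_rates(p20, p20, duration_min = 2)
  expect_equal(sp2$ccpm, 10)
  expect_equal(sp2$wcpm, 0)
  expect_equal(spelling_rates("abc", "", duration_min = 1)$ccpm, 0)
  expect_error(spelling_rates("a", "a", duration_min = 0), "positive")
})

test_that("each correct character consumes at least two true-positive clicks", {
  log <- run_closed_loop(speller_layout(), scan_config(), user_config(),
                         click_detector_sim(), prompts = "to do", seed = 3)
  al <- align_events(sort(log$grasp_onsets_ms), log$clicks,
                     duration_min = log$duration_min)
  sp <- spelling_rates(log$transcripts$prompt, log$transcripts$typed,
                       duration_min = log$duration_min, n_typos = log$n_typos)
  expect_gte(al$n_tp, 2 * sp$n_correct_chars)
})

test_that("BCa bootstrap is seeded, degenerate-safe and sane on a known sample", {
  x <- c(2, 4, 4, 5, 7, 9, 12, 12, 13, 15)
  a <- bootstrap_ci(x, n_replicates = 2000, seed = 7)
  b <- bootstrap_ci(x, n_replicates = 2000, seed = 7)
  expect_identical(a, b)
  expect_lt(a$lower, mean(x))
  expect_gt(a$upper, mean(x))
  expect_true(a$lower > min(x) && a$upper < max(x))
  expect_warning(c0 <- bootstrap_ci(rep(3, 5)), "constant")
  expect_equal(c(c0$lower, c0$upper), c(3, 3))
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("rank-sum z agrees with wilcox.test and Holm adjustment is monotone", {
  set.seed(11)
  a <- rnorm(9); b <- rnorm(9) + 3             # clearly shifted, delta = 3 SD
  rs <- rank_sum_test(a, b)
  expect_lt(rs$p_value, 0.01)
  # cross-check the normal-approximation p against the stats oracle
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(rs$p_value, wt$p.value, tolerance = 1e-10)
  # identical groups: no shift, p near 1
  x <- rnorm(12)
  expect_gte(rank_sum_test(x, x)$p_value, 0.9)
  # Holm-adjusted p >= raw p for every member of the family
  fam <- compare_groups(list(shifted = list(a, b),
                             null1 = list(rnorm(8), rnorm(8)),
                             null2 = list(rnorm(8), rnorm(8))))
  expect_true(all(fam$p_holm >= fam$p_value))
  expect_equal(fam$p_holm, stats::p.adjust(fam$p_value, "holm"))
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})
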