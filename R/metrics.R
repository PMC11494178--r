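#' Match clicks to attempted grasps
#'
#' A click is a true positive when it appears on screen within
#' `tp_window_ms` (inclusive) after the onset of an attempted grasp. Matching
#' is greedy earliest-click-first with at most one click per grasp; grasps
#' with no matched click are false negatives, and clicks matched to no grasp
#' are false positives.
#'
#' @param grasp_onsets_ms Time-sorted attempted-grasp onset times, ms.
#' @param clicks Tibble with `onscreen_t_ms` (and optionally `detect_t_ms`),
#'   time-sorted.
#' @param tp_window_ms True-positive window after each onset, ms (default
#'   1500, boundary inclusive).
#' @param duration_min Session length in minutes (for rates).
#' @return An object of class `event_alignment`: list with `matches` (tibble:
#'   `grasp_onset_ms`, `onscreen_t_ms`, `detect_t_ms`), `fn_onsets_ms`,
#'   `fp_clicks` (tibble), counts `n_tp`, `n_fp`, `n_fn`, `n_grasps`, and
#'   `duration_min`.
#' @export
align_events <- function(grasp_onsets_ms, clicks, tp_window_ms = 1500,
                         duration_min) {
  if (is.unsorted(grasp_onsets_ms)) abort("grasp onsets must be time-sorted")
  if (nrow(clicks) && is.unsorted(clicks$onscreen_t_ms)) {
    abort("clicks must be time-sorted")
  }
  if (!"detect_t_ms" %in% names(clicks)) clicks$detect_t_ms <- NA_real_
  used <- rep(FALSE, nrow(clicks))
  rows <- list()
  fn <- numeric(0)
  for (g in grasp_onsets_ms) {
    cand <- which(!used & clicks$onscreen_t_ms >= g &
                    clicks$onscreen_t_ms <= g + tp_window_ms)
    if (length(cand)) {
      j <- cand[1]                      # greedy earliest click
      used[j] <- TRUE
      rows[[length(rows) + 1]] <- tibble(grasp_onset_ms = g,
                                         onscreen_t_ms = clicks$onscreen_t_ms[j],
                                         detect_t_ms = clicks$detect_t_ms[j])
    } else {
      fn <- c(fn, g)
    }
  }
  matches <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(grasp_onset_ms = numeric(0), onscreen_t_ms = numeric(0),
           detect_t_ms = numeric(0))
  structure(list(matches = matches, fn_onsets_ms = fn,
                 fp_clicks = clicks[!used, , drop = FALSE],
                 n_tp = nrow(matches), n_fp = sum(!used), n_fn = length(fn),
                 n_grasps = length(grasp_onsets_ms),
                 duration_min = duration_min,
                 tp_window_ms = tp_window_ms),
            class = "event_alignment")
}

#' @export
print.event_alignment <- function(x, ...) {
  cat(sprintf("<event_alignment> %d grasps: %d TP, %d FN, %d FP over %.1f min\n",
              x$n_grasps, x$n_tp, x$n_fn, x$n_fp, x$duration_min))
  invisible(x)
}

#' Click-detection sensitivity
#'
#' `sensitivity = N_correct_clicks / N_attempted_grasps * 100%`.
#'
#' @param alignment An [align_events()] result with >= 1 attempted grasp.
#' @return Percentage in `[0, 100]`.
#' @export
click_sensitivity <- function(alignment) {
  if (alignment$n_grasps < 1) {
    abort("sensitivity is undefined with zero attempted grasps")
  }
  alignment$n_tp / alignment$n_grasps * 100
}

#' True- and false-positive click frequencies
#'
#' `TPF = N_TP / T` and `FPF = N_FP / T` with `T` the session duration in
#' minutes; per-hour values are the per-minute values times 60.
#'
#' @param alignment An [align_events()] result with positive duration.
#' @return A tibble: `tpf_per_min`, `fpf_per_min`, `tpf_per_h`, `fpf_per_h`.
#' @export
click_rates <- function(alignment) {
  if (!isTRUE(alignment$duration_min > 0)) abort("session duration must be positive")
  tibble(tpf_per_min = alignment$n_tp / alignment$duration_min,
         fpf_per_min = alignment$n_fp / alignment$duration_min,
         tpf_per_h = alignment$n_tp / alignment$duration_min * 60,
         fpf_per_h = alignment$n_fp / alignment$duration_min * 60)
}

#' Click latency summaries
#'
#' For each true positive: (a) movement onset to algorithmic detection and
#' (b) movement onset to on-screen click; the display offset (b - a) is also
#' summarized.
#'
#' @param alignment An [align_events()] result with >= 1 true positive whose
#'   clicks carry `detect_t_ms`.
#' @return A tibble with one row per latency kind (`detect`, `onscreen`,
#'   `display_offset`): `median_ms`, `mean_ms`, `q1_ms`, `q3_ms`, `n`.
#' @export
latency_stats <- function(alignment) {
  m <- alignment$matches
  if (nrow(m) == 0) abort("no true positives: latencies undefined")
  summarize_lat <- function(kind, x) {
    x <- x[!is.na(x)]
    tibble(latency = kind, median_ms = median(x), mean_ms = mean(x),
           q1_ms = unname(quantile(x, 0.25)), q3_ms = unname(quantile(x, 0.75)),
           n = length(x))
  }
  dplyr::bind_rows(
    summarize_lat("detect", m$detect_t_ms - m$grasp_onset_ms),
    summarize_lat("onscreen", m$onscreen_t_ms - m$grasp_onset_ms),
    summarize_lat("display_offset", m$onscreen_t_ms - m$detect_t_ms))
}

#' Spelling rates from a finalized transcript
#'
#' Position-exact matching against the prompt: a typed character (word) is
#' correct iff it equals the prompt character (whitespace-delimited word) at
#' the same position. Correct characters per minute (CCPM), correct words per
#' minute (CWPM), and wrong characters per minute (WCPM, the rate of
#' character typos made during the session — including ones later deleted).
#'
#' @param prompt Prompted sentence.
#' @param typed Final typed output.
#' @param duration_min Time spent, minutes (> 0).
#' @param n_typos Number of wrong characters output during the session
#'   (defaults to position mismatches in the final output only).
#' @return A tibble: `ccpm`, `wcpm`, `cwpm`, `n_correct_chars`,
#'   `n_correct_words`.
#' @export
spelling_rates <- function(prompt, typed, duration_min, n_typos = NULL) {
  if (!isTRUE(duration_min > 0)) abort("duration must be positive")
  pc <- strsplit(prompt, "")[[1]]
  tc <- strsplit(typed, "")[[1]]
  n <- min(length(pc), length(tc))
  correct_chars <- if (n > 0) sum(pc[seq_len(n)] == tc[seq_len(n)]) else 0L
  pw <- strsplit(trimws(prompt), "\\s+")[[1]]
  tw <- strsplit(trimws(typed), "\\s+")[[1]]
  nw <- min(length(pw), length(tw))
  correct_words <- if (nw > 0) sum(pw[seq_len(nw)] == tw[seq_len(nw)]) else 0L
  if (is.null(n_typos)) {
    n_typos <- (if (n > 0) sum(pc[seq_len(n)] != tc[seq_len(n)]) else 0L) +
      max(length(tc) - length(pc), 0L)
  }
  tibble(ccpm = correct_chars / duration_min,
         wcpm = n_typos / duration_min,
         cwpm = correct_words / duration_min,
         n_correct_chars = correct_chars, n_correct_words = correct_words)
}

#' Evaluate a closed-loop session log
#'
#' Runs event alignment and all performance metrics over a [run_closed_loop()]
#' session (or any log with the same fields).
#'
#' @param session A `session_log`.
#' @param tp_window_ms True-positive window, ms.
#' @return An object of class `bci_performance`: tibble with one row per
#'   metric (`metric`, `value`, `unit`), plus the alignment as an attribute.
#' @export
evaluate_session <- function(session, tp_window_ms = 1500) {
  al <- align_events(session$grasp_onsets_ms, session$clicks,
                     tp_window_ms = tp_window_ms,
                     duration_min = session$duration_min)
  rates <- click_rates(al)
  rows <- tibble(metric = c("sensitivity", "tpf", "fpf"),
                 value = c(click_sensitivity(al), rates$tpf_per_min,
                           rates$fpf_per_min),
                 unit = c("%", "per_min", "per_min"))
  if (al$n_tp > 0 && any(!is.na(al$matches$detect_t_ms))) {
    ls <- latency_stats(al)
    rows <- dplyr::bind_rows(rows, tibble(
      metric = paste0("latency_", ls$latency, "_median"),
      value = ls$median_ms / 1000, unit = "s"))
  }
  if (nrow(session$transcripts) > 0) {
    tr <- session$transcripts
    sp <- spelling_rates(paste(tr$prompt, collapse = " "),
                         paste(tr$typed, collapse = " "),
                         duration_min = session$duration_min,
                         n_typos = session$n_typos)
    rows <- dplyr::bind_rows(rows, tibble(
      metric = c("ccpm", "wcpm", "cwpm"),
      value = c(sp$ccpm, sp$wcpm, sp$cwpm),
      unit = "per_min"))
  }
  structure(rows, alignment = al, class = c("bci_performance", class(rows)))
}

#' Bias-corrected and accelerated bootstrap CI for the mean
#'
#' BCa interval with the acceleration estimated by jackknife; seeded and
#' reproducible. A constant sample yields the degenerate interval `[c, c]`
#' with a warning.
#'
#' @param values Numeric sample (>= 2 values).
#' @param n_replicates Bootstrap replicates (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return A tibble: `mean`, `lower`, `upper`, `conf`, `n_replicates`.
#' @export
bootstrap_ci <- function(values, n_replicates = 10000, conf = 0.95, seed = 1) {
  n <- length(values)
  if (n < 2) abort("need at least 2 values")
  theta <- mean(values)
  if (sd(values) == 0) {
    warn("constant sample: degenerate BCa interval")
    return(tibble(mean = theta, lower = theta, upper = theta,
                  conf = conf, n_replicates = n_replicates))
  }
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_replicates, replace = TRUE), nrow = n)
    colMeans(matrix(values[idx], nrow = n))
  })
  # bias correction
  z0 <- qnorm((sum(boots < theta) + 0.5 * sum(boots == theta)) / n_replicates)
  # acceleration via jackknife
  jk <- (sum(values) - values) / (n - 1)
  d <- mean(jk) - jk
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  alpha <- (1 - conf) / 2
  zl <- qnorm(alpha); zu <- qnorm(1 - alpha)
  p_lo <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  p_hi <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  ci <- unname(quantile(boots, c(p_lo, p_hi), type = 6))
  tibble(mean = theta, lower = ci[1], upper = ci[2], conf = conf,
         n_replicates = n_replicates)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Rank-sum test with the normal approximation: the statistic reported is the
#' z value (tie-corrected variance, continuity correction), with the
#' two-sided p from the normal distribution. The exact small-sample p from
#' [stats::wilcox.test()] is available via `exact = TRUE`.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact Use the exact distribution instead of the normal
#'   approximation (no ties only).
#' @return A tibble: `statistic` (z), `p_value`, `n_a`, `n_b`.
#' @export
rank_sum_test <- function(a, b, exact = FALSE) {
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  if (exact) {
    wt <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    return(tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                  n_a = length(a), n_b = length(b)))
  }
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])                      # rank sum of group a
  mu <- na * (nb + na + 1) / 2
  ties <- table(r)
  tie_adj <- sum(ties^3 - ties) / ((na + nb) * (na + nb - 1))
  sigma2 <- na * nb / 12 * ((na + nb + 1) - tie_adj)
  diffw <- w - mu
  cc <- sign(diffw) * 0.5                        # continuity correction
  z <- if (sigma2 > 0) (diffw - cc) / sqrt(sigma2) else 0
  tibble(statistic = z, p_value = min(1, 2 * pnorm(-abs(z))),
         n_a = na, n_b = nb)
}

#' Compare groups across a family of tests with Holm correction
#'
#' Runs [rank_sum_test()] for each named pair and adjusts the two-sided
#' p-values across the family with the Holm step-down procedure.
#'
#' @param pairs Named list; each element is `list(a, b)` (or an unnamed
#'   2-element list of numeric vectors).
#' @return A tibble: `comparison`, `statistic`, `p_value`, `p_holm`.
#' @export
compare_groups <- function(pairs) {
  if (!length(pairs)) abort("empty family of tests")
  nm <- names(pairs)
  if (is.null(nm)) nm <- paste0("test", seq_along(pairs))
  res <- purrr::map2_dfr(pairs, nm, function(p, n) {
    dplyr::mutate(rank_sum_test(p[[1]], p[[2]]), comparison = n,
                  .before = 1)
  })
  dplyr::mutate(res, p_holm = stats::p.adjust(.data$p_value, method = "holm"))
}
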