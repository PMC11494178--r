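#' Labeling configuration
#'
#' Grasp labels are assigned to feature frames falling between and including
#' `onset_s + shift` and `offset_s + shift` relative to the Go cue of each
#' trial, where `shift` is the trial's time-warp shift; rest labels apply at
#' all other times. The study's estimated modulation window was 0.3-1.1 s
#' after the Go cue, i.e. 800 ms of grasp-labeled data per trial.
#'
#' @param onset_s Modulation onset relative to the cue, seconds.
#' @param offset_s Modulation offset relative to the cue, seconds.
#' @param trial_window_s Length-2, the trial segment (relative to the cue)
#'   used for realignment and onset/offset estimation.
#' @return An object of class `label_config`.
#' @export
label_config <- function(onset_s = 0.3, offset_s = 1.1,
                         trial_window_s = c(-1.0, 2.5)) {
  if (onset_s >= offset_s) abort("onset_s must be before offset_s")
  if (onset_s < trial_window_s[1] || offset_s > trial_window_s[2]) {
    abort("label window must lie inside the trial window")
  }
  structure(list(onset_s = onset_s, offset_s = offset_s,
                 trial_window_s = trial_window_s),
            class = "label_config")
}

#' Cut cue-aligned trial segments from a feature stream
#'
#' @param frames Feature tibble from [stream_features()].
#' @param cue_onsets_ms Strictly increasing cue times, ms.
#' @param cfg A [label_config()].
#' @param step_ms Frame cadence, ms.
#' @return A list: `tensor` (trials x frames x channels array of high-gamma
#'   values), `rel_t_ms` (frame times relative to the cue), `frame_index`
#'   (trials x frames matrix of row indices into `frames`).
#' @export
trial_tensor <- function(frames, cue_onsets_ms, cfg = label_config(),
                         step_ms = 100) {
  if (is.unsorted(cue_onsets_ms, strictly = TRUE)) {
    abort("cue onsets must be strictly increasing")
  }
  mat <- feature_matrix(frames)
  t_ms <- frames$t_ms
  n_f <- floor(diff(cfg$trial_window_s) * 1000 / step_ms) + 1
  n_tr <- length(cue_onsets_ms)
  tens <- array(NA_real_, c(n_tr, n_f, ncol(mat)))
  idx <- matrix(NA_integer_, n_tr, n_f)
  for (j in seq_len(n_tr)) {
    lo <- cue_onsets_ms[j] + cfg$trial_window_s[1] * 1000
    i0 <- which(t_ms >= lo)[1]
    if (is.na(i0) || i0 + n_f - 1 > length(t_ms)) {
      abort(sprintf("trial %d does not fit inside the feature stream", j))
    }
    sel <- i0:(i0 + n_f - 1)
    tens[j, , ] <- mat[sel, ]
    idx[j, ] <- sel
  }
  rel <- t_ms[idx[1, ]] - cue_onsets_ms[1]
  list(tensor = tens, rel_t_ms = rel, frame_index = idx)
}

#' Select the most strongly modulated channels
#'
#' Ranks channels by the trial-averaged peak high-gamma value in the
#' (0, 1.5] s interval after the cue and returns the indices of the top
#' `n_select`. Ties break toward the lowest channel index. This automates the
#' qualitative channel screen used to restrict the time-warp fit to channels
#' that actually modulate.
#'
#' @param trials A [trial_tensor()] result (>= 5 trials recommended).
#' @param n_select Number of channels to keep.
#' @return Sorted integer channel indices, length `n_select`.
#' @export
select_modulated_channels <- function(trials, n_select) {
  tens <- trials$tensor
  if (n_select > dim(tens)[3]) abort("n_select exceeds channel count")
  post <- which(trials$rel_t_ms > 0 & trials$rel_t_ms <= 1500)
  # per trial & channel: peak over the post-cue window, then average trials
  peak <- apply(tens[, post, , drop = FALSE], c(1, 3), max)
  score <- colMeans(peak)
  sort(order(-score, seq_along(score))[seq_len(n_select)])
}

# Shift a trial trace (frames x channels) by s frames: positive s means the
# trial happened late, so the aligned trace is the original advanced by s.
shift_trace <- function(x, s) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, ncol(x))
  src <- seq_len(n) + s
  ok <- src >= 1 & src <= n
  out[ok, ] <- x[src[ok], , drop = FALSE]
  out
}

# Sum over channels of Pearson correlation between two traces on rows where
# both are complete; NA-safe, zero for degenerate traces.
trace_similarity <- function(a, b) {
  ok <- complete.cases(a) & complete.cases(b)
  if (sum(ok) < 3) return(-Inf)
  s <- 0
  for (c in seq_len(ncol(a))) {
    sa <- sd(a[ok, c]); sb <- sd(b[ok, c])
    if (sa > 0 && sb > 0) s <- s + stats::cor(a[ok, c], b[ok, c])
  }
  s
}

#' Fit a shift-only time-warp across trials
#'
#' Finds one integer frame shift per trial that maximizes the agreement of
#' each trial's high-gamma trace (over the selected channels) with an
#' iteratively refined cross-trial average template. Coordinate ascent: align
#' every trial to the current template, re-average, repeat until the shifts
#' stop changing or `max_iter` is reached. Shifts are identified only up to a
#' global constant; downstream they are applied identically across all
#' channels.
#'
#' @param trials A [trial_tensor()] result (>= 2 trials).
#' @param channels Channel indices to fit on (from
#'   [select_modulated_channels()]); default all.
#' @param max_shift_frames Maximum |shift| in frames (default 5).
#' @param max_iter Maximum coordinate-ascent sweeps (default 50).
#' @return An object of class `shift_warp`: list with `shift_frames`
#'   (per-trial integer shifts), `template` (frames x selected-channels
#'   aligned average), `channels_used`, `converged`.
#' @export
fit_shift_warp <- function(trials, channels = NULL, max_shift_frames = 5,
                           max_iter = 50) {
  tens <- trials$tensor
  n_tr <- dim(tens)[1]
  if (n_tr < 2) abort("need at least 2 trials to fit a shift warp")
  if (is.null(channels)) channels <- seq_len(dim(tens)[3])
  sub <- tens[, , channels, drop = FALSE]
  shifts <- integer(n_tr)
  cand <- -max_shift_frames:max_shift_frames
  template <- apply(sub, c(2, 3), mean)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    new_shifts <- shifts
    for (j in seq_len(n_tr)) {
      sims <- vapply(cand, function(s) {
        trace_similarity(shift_trace(matrix(sub[j, , ], dim(sub)[2]), s), template)
      }, numeric(1))
      # ties break toward the smallest |shift|, then the earlier shift
      best <- cand[order(-sims, abs(cand), cand)][1]
      new_shifts[j] <- best
    }
    aligned <- vapply(seq_len(n_tr), function(j) {
      shift_trace(matrix(sub[j, , ], dim(sub)[2]), new_shifts[j])
    }, matrix(0, dim(sub)[2], length(channels)))
    template <- apply(aligned, c(1, 2), mean, na.rm = TRUE)
    if (all(new_shifts == shifts) && it > 1) { converged <- TRUE; break }
    shifts <- new_shifts
  }
  structure(list(shift_frames = shifts, template = template,
                 rel_t_ms = trials$rel_t_ms,
                 channels_used = channels, converged = converged),
            class = "shift_warp")
}

#' @export
print.shift_warp <- function(x, ...) {
  cat(sprintf("<shift_warp> %d trials, shifts in [%d, %d], %s\n",
              length(x$shift_frames), min(x$shift_frames), max(x$shift_frames),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Estimate modulation onset and offset from an aligned trial average
#'
#' Automated surrogate for visual onset/offset determination: the onset
#' (offset) is the first (last) time the channel-averaged aligned trace
#' crosses `threshold_fraction` of its peak elevation above the rest median.
#' An explicit `override` (e.g. the study's 0.3 / 1.1 s) is returned verbatim.
#'
#' @param warp A [fit_shift_warp()] result.
#' @param threshold_fraction Fraction of peak elevation (default 0.5).
#' @param override Optional length-2 numeric `(onset_s, offset_s)` returned
#'   as-is.
#' @return Named numeric: `onset_s`, `offset_s` (relative to the cue).
#' @export
estimate_onset_offset <- function(warp, threshold_fraction = 0.5,
                                  override = NULL) {
  if (!is.null(override)) {
    return(c(onset_s = override[1], offset_s = override[2]))
  }
  trace <- rowMeans(warp$template, na.rm = TRUE)
  rel <- warp$rel_t_ms
  base <- median(trace[rel <= 0], na.rm = TRUE)
  elev <- trace - base
  pk <- max(elev, na.rm = TRUE)
  if (!is.finite(pk) || pk <= 0 || sd(trace, na.rm = TRUE) == 0) {
    abort("flat trial-average trace: cannot estimate onset/offset")
  }
  above <- which(elev >= threshold_fraction * pk)
  c(onset_s = rel[min(above)] / 1000, offset_s = rel[max(above)] / 1000)
}

#' Assign rest/grasp labels to feature frames
#'
#' A frame is labeled grasp when its timestamp lies between and including
#' `cue + onset + shift` and `cue + offset + shift` for some trial (shifts in
#' 100 ms frame units, applied identically across channels); all other frames
#' are rest.
#'
#' @param frames Feature tibble.
#' @param cue_onsets_ms Cue times, ms.
#' @param shifts Per-trial integer frame shifts (recycled 0 if omitted).
#' @param cfg A [label_config()].
#' @param step_ms Frame cadence, ms.
#' @return The input tibble plus `label` (factor rest/grasp) and `trial_id`
#'   (integer, `NA` for rest frames).
#' @export
assign_labels <- function(frames, cue_onsets_ms, shifts = NULL,
                          cfg = label_config(), step_ms = 100) {
  if (is.null(shifts)) shifts <- integer(length(cue_onsets_ms))
  if (length(shifts) != length(cue_onsets_ms)) {
    abort("one shift per trial is required")
  }
  lo <- cue_onsets_ms + cfg$onset_s * 1000 + shifts * step_ms
  hi <- cue_onsets_ms + cfg$offset_s * 1000 + shifts * step_ms
  if (any(head(hi, -1) >= tail(lo, -1))) {
    abort("grasp windows of adjacent trials overlap")
  }
  t_ms <- frames$t_ms
  label <- rep("rest", length(t_ms))
  trial_id <- rep(NA_integer_, length(t_ms))
  for (j in seq_along(lo)) {
    in_win <- t_ms >= lo[j] & t_ms <= hi[j]
    label[in_win] <- "grasp"
    trial_id[in_win] <- j
  }
  dplyr::mutate(frames, label = factor(label, levels = c("rest", "grasp")),
                trial_id = trial_id)
}

#' Partition labeled frames into balanced contiguous folds
#'
#' Splits the labeled stream into `k` contiguous time spans containing (as
#' near as possible) equal numbers of grasp frames, then randomly downsamples
#' rest frames within each fold to match that fold's grasp count, so every
#' fold is class-balanced and all retained samples in a fold are contiguous in
#' time. Downsampling removes only rest frames.
#'
#' @param labeled Output of [assign_labels()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the rest-frame downsampling.
#' @return The input tibble plus `fold` (integer, `NA` outside all folds —
#'   never happens here) and `retained` (logical; dropped rest frames are
#'   `FALSE`).
#' @export
balance_and_fold <- function(labeled, k = 10, seed = 1) {
  stopifnot(all(c("label", "t_ms") %in% names(labeled)))
  ord <- order(labeled$t_ms)
  labeled <- labeled[ord, ]
  is_grasp <- labeled$label == "grasp"
  g <- sum(is_grasp)
  if (g < k) abort("fewer grasp samples than folds")
  if (g == 0 || g == nrow(labeled)) abort("both classes must be present")
  # fold quota: distribute grasp frames as evenly as possible
  quota <- rep(g %/% k, k) + c(rep(1, g %% k), rep(0, k - g %% k))
  cum_g <- cumsum(is_grasp)
  bounds <- cumsum(quota)
  # fold of each frame: first fold whose cumulative grasp quota covers it
  fold <- findInterval(cum_g, bounds + 0.5) + 1L
  # frames before the first grasp belong to fold 1 by construction; frames
  # after the last quota boundary stay in fold k
  fold[fold > k] <- k
  retained <- rep(TRUE, nrow(labeled))
  with_seed(seed, {
    for (f in seq_len(k)) {
      in_f <- which(fold == f)
      gr <- in_f[is_grasp[in_f]]
      re <- in_f[!is_grasp[in_f]]
      if (length(re) > length(gr)) {
        drop <- sample(re, length(re) - length(gr))
        retained[drop] <- FALSE
      }
    }
  })
  dplyr::mutate(labeled, fold = fold, retained = retained)
}
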