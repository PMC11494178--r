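#' Voting-window click detector configuration
#'
#' Each per-100 ms classification enters a running vote buffer; a click fires
#' when the number of grasp votes in the buffer reaches the threshold, after
#' which a refractory lock-out suppresses further clicks and the vote buffer
#' is cleared (clearing prevents an immediate re-fire when the lock-out
#' expires, and votes are not accumulated during lock-out). The study used a
#' 10-vote window with a 10-vote threshold for the communication board and a
#' 7-vote window with a 7-vote (later 4-vote) threshold for the speller, with
#' a 1 s lock-out. With a 4-vote threshold the minimum latency from the onset
#' of grasp classifications to a click is 400 ms (four sequential grasp
#' votes at the 100 ms cadence).
#'
#' @param window Vote buffer length.
#' @param threshold Grasp votes required (`1 <= threshold <= window`; reaching
#'   the threshold fires, so an all-window threshold is satisfiable).
#' @param lockout_ms Refractory period after each click, ms.
#' @param onscreen_delay_ms Constant delay added to the algorithmic detection
#'   time to model the on-screen click in offline simulation (the study
#'   measured ~200 ms of display overhead).
#' @param step_ms Classification cadence, ms.
#' @return An object of class `voting_config`.
#' @export
voting_config <- function(window = 7, threshold = 4, lockout_ms = 1000,
                          onscreen_delay_ms = 200, step_ms = 100) {
  if (threshold < 1 || threshold > window) {
    abort("threshold must satisfy 1 <= threshold <= window")
  }
  if (lockout_ms < 0) abort("lockout_ms must be >= 0")
  structure(list(window = as.integer(window), threshold = as.integer(threshold),
                 lockout_ms = lockout_ms, onscreen_delay_ms = onscreen_delay_ms,
                 step_ms = step_ms),
            class = "voting_config")
}

#' Fresh detector state
#' @param cfg A [voting_config()].
#' @return A `detector_state`: empty vote ring buffer and expired lock-out.
#' @export
detector_state <- function(cfg) {
  structure(list(votes = integer(0), lockout_until = -Inf, last_t = -Inf),
            class = "detector_state")
}

#' Advance the detector by one classification
#'
#' Appends the vote to the ring buffer (unless within lock-out, during which
#' votes are discarded), fires a click when grasp votes reach the threshold,
#' then clears the buffer and starts the lock-out.
#'
#' @param state A [detector_state()].
#' @param classification `"grasp"`/`"rest"` (or 1/0).
#' @param t_ms Timestamp of this classification (packet end); must be
#'   monotonically increasing.
#' @param cfg A [voting_config()].
#' @return A list: `state` (updated) and `click` (`NULL` or a one-row tibble
#'   with `detect_t_ms`, `onscreen_t_ms`).
#' @export
vote_step <- function(state, classification, t_ms, cfg) {
  if (t_ms <= state$last_t) abort("timestamps must be strictly increasing")
  state$last_t <- t_ms
  vote <- if (is.character(classification) || is.factor(classification)) {
    as.integer(as.character(classification) == "grasp")
  } else as.integer(classification != 0)
  click <- NULL
  if (t_ms >= state$lockout_until) {
    state$votes <- c(state$votes, vote)
    if (length(state$votes) > cfg$window) {
      state$votes <- state$votes[-1]
    }
    if (sum(state$votes) >= cfg$threshold) {
      click <- tibble(detect_t_ms = t_ms,
                      onscreen_t_ms = t_ms + cfg$onscreen_delay_ms)
      state$votes <- integer(0)
      state$lockout_until <- t_ms + cfg$lockout_ms
    }
  }
  list(state = state, click = click)
}

#' Run the voting detector over a classification stream
#'
#' @param labels Vector of classifications (`"rest"`/`"grasp"`, factor, or
#'   0/1) in time order.
#' @param t_ms Timestamps (packet ends), same length.
#' @param cfg A [voting_config()].
#' @return A tibble of click events: `detect_t_ms`, `onscreen_t_ms`.
#' @export
run_votes <- function(labels, t_ms, cfg) {
  st <- detector_state(cfg)
  clicks <- list()
  for (i in seq_along(t_ms)) {
    out <- vote_step(st, labels[i], t_ms[i], cfg)
    st <- out$state
    if (!is.null(out$click)) clicks[[length(clicks) + 1]] <- out$click
  }
  if (length(clicks)) dplyr::bind_rows(clicks) else
    tibble(detect_t_ms = numeric(0), onscreen_t_ms = numeric(0))
}

#' Full detection pipeline: features -> classifier -> votes -> clicks
#'
#' Composes [predict_stream()] and [run_votes()]. Deterministic; output is
#' invariant to how the underlying signal was packetized because the feature
#' stream is.
#'
#' @param model A trained `grasp_model`.
#' @param frames Feature tibble from [stream_features()].
#' @param cfg A [voting_config()].
#' @return A tibble of click events (`detect_t_ms`, `onscreen_t_ms`).
#' @export
run_detector <- function(model, frames, cfg = voting_config()) {
  preds <- predict_stream(model, frames)
  run_votes(preds$label, preds$t_ms, cfg)
}

#' Harvest a training dataset from a spelling session
#'
#' Builds rest/grasp labels around the session's attempted-movement onsets
#' rather than Go cues: grasps occurring less than `min_gap_ms` (default 3 s,
#' the minimum jittered inter-stimulus interval) after a preceding attempted
#' grasp are excluded from training entirely, and the remaining onsets are
#' labeled with the modulation window `(onset_s, offset_s)` relative to
#' movement start.
#'
#' @param frames Feature tibble of the spelling-session recording.
#' @param grasp_onsets_ms Ground-truth attempted-grasp onset times, ms.
#' @param onset_s,offset_s Label window relative to movement onset, seconds.
#'   Defaults 0 and 0.8 (the modulation duration).
#' @param min_gap_ms Exclusion rule: drop grasps closer than this to their
#'   predecessor.
#' @param step_ms Frame cadence, ms.
#' @return A list: `labeled` (feature tibble + `label`, `trial_id`),
#'   `kept_onsets_ms`, `excluded_onsets_ms`.
#' @export
harvest_training_from_spelling <- function(frames, grasp_onsets_ms,
                                           onset_s = 0, offset_s = 0.8,
                                           min_gap_ms = 3000, step_ms = 100) {
  if (length(grasp_onsets_ms) == 0) abort("empty session log: no grasp onsets")
  on <- sort(grasp_onsets_ms)
  keep <- logical(length(on))
  last_kept <- -Inf
  for (i in seq_along(on)) {
    # the rule excludes grasps < min_gap after ANY preceding attempted grasp
    prev <- if (i > 1) on[i - 1] else -Inf
    keep[i] <- (on[i] - prev) >= min_gap_ms
    if (i == 1) keep[i] <- TRUE
  }
  kept <- on[keep]
  cfg <- label_config(onset_s = onset_s, offset_s = offset_s,
                      trial_window_s = c(-1, 2.5))
  # reuse the cue-based labeler with cues = movement onsets
  labeled <- assign_labels(frames, kept, shifts = NULL, cfg = cfg,
                           step_ms = step_ms)
  # data around excluded grasps is excluded from labeling altogether (it is
  # neither clean rest nor a usable grasp trial)
  excl <- on[!keep]
  if (length(excl)) {
    for (e in excl) {
      bad <- labeled$t_ms >= e + onset_s * 1000 - 500 &
        labeled$t_ms <= e + offset_s * 1000 + 500
      labeled$label[bad] <- NA
    }
  }
  list(labeled = labeled, kept_onsets_ms = kept,
       excluded_onsets_ms = excl)
}
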