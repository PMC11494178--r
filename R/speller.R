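#' Switch-scanning key layout
#'
#' A grid of keys by row. Special key identifiers: `SPACE`, `DEL` (delete one
#' character), `A-DEL` (auto-delete: remove the last whole word), `ENTER`
#' (finalize the sentence), `W1..Wn` (word-autocomplete slots), `L1..Ln`
#' (letter-autocomplete slots). The default speller layout has one
#' word-suggestion row, one letter-suggestion row, the alphabet, and the
#' control keys; the communication-board mode is the same machine with a
#' layout of icon keys only.
#'
#' @param rows A list of character vectors (one per row); `NULL` for the
#'   default speller grid.
#' @param mode `"speller"` or `"board"`.
#' @return An object of class `speller_layout`.
#' @export
speller_layout <- function(rows = NULL, mode = c("speller", "board")) {
  mode <- match.arg(mode)
  if (is.null(rows)) {
    rows <- if (mode == "speller") {
      list(c("W1", "W2", "W3", "W4"),
           c("L1", "L2", "L3", "L4"),
           c("a", "b", "c", "d", "e", "f"),
           c("g", "h", "i", "j", "k", "l"),
           c("m", "n", "o", "p", "q", "r"),
           c("s", "t", "u", "v", "w", "x"),
           c("y", "z", "SPACE", "."),
           c("DEL", "A-DEL", "ENTER"))
    } else {
      list(c("icon01", "icon02", "icon03", "icon04"),
           c("icon05", "icon06", "icon07", "icon08"),
           c("icon09", "icon10", "icon11", "icon12"),
           c("icon13", "icon14", "icon15", "icon16"))
    }
  }
  if (!length(rows) || any(!lengths(rows))) abort("rows must be non-empty")
  keys <- unlist(rows)
  if (anyDuplicated(keys)) abort("key identifiers must be unique")
  if (mode == "speller" && !all(c("DEL", "A-DEL", "ENTER") %in% keys)) {
    abort("speller mode requires DEL, A-DEL and ENTER keys")
  }
  structure(list(rows = rows, mode = mode), class = "speller_layout")
}

#' Scan timing configuration
#'
#' @param scan_rate_hz Row/column highlight steps per second (default 0.67,
#'   i.e. ~1.49 s per step).
#' @param preselect_rows Dummy steps at the start of each row-scanning cycle
#'   (default 3), giving the user preparation time before the first row.
#' @param preselect_cols Dummy steps at the start of each column-scanning
#'   cycle (default 1).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(scan_rate_hz = 0.67, preselect_rows = 3,
                        preselect_cols = 1) {
  if (scan_rate_hz <= 0) abort("scan_rate_hz must be positive")
  structure(list(scan_rate_hz = scan_rate_hz,
                 step_ms = 1000 / scan_rate_hz,
                 preselect_rows = as.integer(preselect_rows),
                 preselect_cols = as.integer(preselect_cols)),
            class = "scan_config")
}

#' Fresh speller state
#'
#' @param layout A [speller_layout()].
#' @param prompt Sentence the user is asked to type (may be `""` in board
#'   mode).
#' @return An object of class `speller_state`. `phase` is `"row"` or `"col"`;
#'   `pos` counts scan steps within the current cycle, with positions up to
#'   the pre-selection count highlighting nothing.
#' @export
speller_state <- function(layout, prompt = "") {
  structure(list(phase = "row", pos = 0L, sel_row = NA_integer_,
                 typed = "", prompt = prompt,
                 pending_error = NA_character_,  # NA / "char" / "word"
                 suggestions = list(words = character(0), letters = character(0))),
            class = "speller_state")
}

# Highlighted item of the current position: list(kind = "none"/"row"/"key",
# index or key id).
highlighted <- function(state, layout, cfg) {
  if (state$phase == "row") {
    if (state$pos <= cfg$preselect_rows) return(list(kind = "none"))
    list(kind = "row", row = as.integer(state$pos - cfg$preselect_rows))
  } else {
    if (state$pos <= cfg$preselect_cols) return(list(kind = "none"))
    row <- layout$rows[[state$sel_row]]
    list(kind = "key", key = row[state$pos - cfg$preselect_cols])
  }
}

#' Advance the scan by one step
#'
#' Consumes a pre-selection step or moves the highlight to the next row or
#' key, wrapping cyclically (a full cycle is the pre-selection steps followed
#' by every row/key).
#'
#' @param state A [speller_state()].
#' @param layout A [speller_layout()].
#' @param cfg A [scan_config()].
#' @return The updated state.
#' @export
advance <- function(state, layout, cfg) {
  n <- if (state$phase == "row") {
    cfg$preselect_rows + length(layout$rows)
  } else {
    cfg$preselect_cols + length(layout$rows[[state$sel_row]])
  }
  state$pos <- as.integer(state$pos %% n + 1L)
  state
}

# Execute a key: returns list(state, action tibble-row description).
execute_key <- function(state, key) {
  action <- key
  out_char <- NA_character_
  if (key == "DEL") {
    if (nchar(state$typed) > 0) {
      state$typed <- substr(state$typed, 1, nchar(state$typed) - 1)
    }
  } else if (key == "A-DEL") {
    state$typed <- sub("\\S+\\s*$", "", state$typed)
  } else if (key == "ENTER") {
    # handled by the session loop (sentence finalization)
  } else if (grepl("^W\\d+$", key)) {
    i <- as.integer(sub("W", "", key))
    w <- state$suggestions$words[i]
    if (!is.na(w) && nzchar(w)) {
      # replace the current partial word with the completed word plus a space
      state$typed <- paste0(sub("\\S*$", "", state$typed), w, " ")
      out_char <- w
    }
  } else if (grepl("^L\\d+$", key)) {
    i <- as.integer(sub("L", "", key))
    l <- state$suggestions$letters[i]
    if (!is.na(l) && nzchar(l)) {
      state$typed <- paste0(state$typed, l)
      out_char <- l
    }
  } else if (key == "SPACE") {
    state$typed <- paste0(state$typed, " ")
    out_char <- " "
  } else {
    state$typed <- paste0(state$typed, key)
    out_char <- key
  }
  # error bookkeeping: output not matching the prompt prefix turns red and
  # must be deleted before continuing
  if (!startsWith(state$prompt, state$typed) && nzchar(state$prompt)) {
    state$pending_error <- if (grepl("^W\\d+$", key)) "word" else "char"
  } else {
    state$pending_error <- NA_character_
  }
  list(state = state, key = key, out_char = out_char)
}

#' Apply a click to the speller
#'
#' In row-scan phase a click selects the highlighted row and starts column
#' scanning; in column-scan phase it executes the highlighted key and
#' restarts the cycle. Clicks landing on a pre-selection step are ignored.
#'
#' @inheritParams advance
#' @param engine Autocomplete engine (see [default_suggest_engine()]), used to
#'   refresh suggestions after a key executes.
#' @return A list: `state`, `action` (`"none"`, `"row"`, or the executed key
#'   id), `out_char` (character/word appended, or `NA`).
#' @export
apply_click <- function(state, layout, cfg, engine = NULL) {
  h <- highlighted(state, layout, cfg)
  if (h$kind == "none") {
    return(list(state = state, action = "none", out_char = NA_character_))
  }
  if (h$kind == "row") {
    state$phase <- "col"
    state$sel_row <- h$row
    state$pos <- 0L
    return(list(state = state, action = "row", out_char = NA_character_))
  }
  res <- execute_key(state, h$key)
  state <- res$state
  state$phase <- "row"
  state$sel_row <- NA_integer_
  state$pos <- 0L
  if (!is.null(engine)) {
    state$suggestions <- suggest(current_word(state$typed), engine,
                                 n_words = slot_count(layout, "W"),
                                 n_letters = slot_count(layout, "L"))
  }
  list(state = state, action = res$key, out_char = res$out_char)
}

current_word <- function(typed) sub("^.*\\s", "", typed)

slot_count <- function(layout, prefix) {
  sum(grepl(paste0("^", prefix, "\\d+$"), unlist(layout$rows)))
}

#' Deterministic word/letter frequency autocomplete engine
#'
#' Built from a small packaged word-frequency table; suggestions are ordered
#' by corpus frequency and are deterministic for a given context. This is the
#' pluggable stand-in for an external language-model service.
#'
#' @return A function `f(context)` returning
#'   `list(words = ..., letters = ...)`: words beginning with the current
#'   partial word, and candidate next letters, both frequency-ordered.
#' @export
default_suggest_engine <- function() {
  path <- system.file("extdata", "word_freq_synthetic.csv", package = "clickbci")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$word), ]
  function(context) {
    context <- tolower(context)
    hit <- tab[startsWith(tab$word, context) & nchar(tab$word) > nchar(context), ]
    letters <- unique(substr(hit$word, nchar(context) + 1, nchar(context) + 1))
    list(words = hit$word, letters = letters)
  }
}

#' Fill suggestion slots from an engine
#'
#' @param context Current partial word (possibly `""`).
#' @param engine An engine function (see [default_suggest_engine()]); engine
#'   failures yield empty suggestions.
#' @param n_words,n_letters Slot counts; engine output is truncated to fit.
#' @return `list(words, letters)` each at most the slot count.
#' @export
suggest <- function(context, engine, n_words = 4, n_letters = 4) {
  res <- tryCatch(engine(context),
                  error = function(e) list(words = character(0),
                                           letters = character(0)))
  list(words = head(res$words, n_words), letters = head(res$letters, n_letters))
}

#' Simulated user configuration
#'
#' Behavioral stand-in for the participant: the user watches the scan, and
#' when the row/column leading toward the next needed character of the prompt
#' is highlighted, attempts a grasp after a uniform reaction latency. After an
#' erroneous output the user targets the appropriate delete key. With
#' probability `error_rate` a click is aimed at a neighboring row/column
#' instead of the correct one.
#'
#' @param reaction_latency_ms Length-2 uniform bounds of the
#'   highlight-to-attempt latency (default 150-450 ms, keeping clicks inside
#'   the 1.5 s true-positive window at the default scan rate).
#' @param error_rate Probability of aiming at the wrong row/column,
#'   `0 <= error_rate < 1`.
#' @param use_suggestions Whether the user selects a word-suggestion slot when
#'   one completes the current word of the prompt.
#' @return An object of class `user_config`.
#' @export
user_config <- function(reaction_latency_ms = c(150, 450), error_rate = 0,
                        use_suggestions = FALSE) {
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must be in [0, 1)")
  structure(list(reaction_latency_ms = reaction_latency_ms,
                 error_rate = error_rate, use_suggestions = use_suggestions),
            class = "user_config")
}

# The key the user currently wants, given the prompt and state.
target_key <- function(state, layout) {
  if (!is.na(state$pending_error)) {
    return(if (state$pending_error == "word") "A-DEL" else "DEL")
  }
  if (state$typed == state$prompt) return("ENTER")
  nxt <- substr(state$prompt, nchar(state$typed) + 1, nchar(state$typed) + 1)
  if (nxt == " ") "SPACE" else nxt
}

# Row index containing a key, or NA.
key_row <- function(layout, key) {
  for (r in seq_along(layout$rows)) {
    if (key %in% layout$rows[[r]]) return(r)
  }
  NA_integer_
}

#' Simulated click detector for closed-loop sessions
#'
#' Converts a user's attempted-grasp time into a detected click with the
#' given sensitivity and latency, and injects false-positive clicks as a
#' Poisson process. An oracle detector is the default (perfect sensitivity,
#' no false positives, the minimum 4-vote algorithmic latency plus the 200 ms
#' on-screen delay).
#'
#' @param sensitivity Probability an attempted grasp produces a click.
#' @param fpf_per_min False-positive click rate per minute.
#' @param detect_latency_ms Movement onset to algorithmic detection, ms.
#' @param onscreen_delay_ms Detection to on-screen click, ms.
#' @return An object of class `sim_detector`.
#' @export
click_detector_sim <- function(sensitivity = 1, fpf_per_min = 0,
                               detect_latency_ms = 400,
                               onscreen_delay_ms = 200) {
  structure(list(sensitivity = sensitivity, fpf_per_min = fpf_per_min,
                 detect_latency_ms = detect_latency_ms,
                 onscreen_delay_ms = onscreen_delay_ms),
            class = "sim_detector")
}

#' Run a closed-loop switch-scanning session
#'
#' Simulates the full loop — scan cycle, user intent, click detection, key
#' execution, autocomplete — over a list of prompted sentences, producing a
#' session log sufficient for every performance metric: ground-truth grasp
#' onsets, clicks (algorithmic and on-screen), selections, typed output and
#' timestamps.
#'
#' @param layout A [speller_layout()].
#' @param scan_cfg A [scan_config()].
#' @param user_cfg A [user_config()].
#' @param detector A [click_detector_sim()].
#' @param prompts Character vector of sentences to type.
#' @param seed Integer seed (reaction latencies, user errors, detector noise).
#' @param engine Autocomplete engine; default [default_suggest_engine()].
#' @param max_steps Hard stop on scan steps (liveness guard for tests).
#' @return An object of class `session_log`: list with `events` (tibble:
#'   `t_ms`, `event`, `detail`), `transcripts` (tibble: `prompt`, `typed`,
#'   `t_start_ms`, `t_end_ms`), `clicks` (tibble: `detect_t_ms`,
#'   `onscreen_t_ms`), `grasp_onsets_ms`, `duration_min`, `n_typos`,
#'   `completed` (logical).
#' @export
run_closed_loop <- function(layout, scan_cfg = scan_config(),
                            user_cfg = user_config(),
                            detector = click_detector_sim(),
                            prompts, seed = 1,
                            engine = default_suggest_engine(),
                            max_steps = 5000) {
  bad <- setdiff(strsplit(tolower(paste(prompts, collapse = "")), "")[[1]],
                 c(unlist(layout$rows), " "))
  if (length(bad)) {
    abort(paste0("prompt contains characters absent from the layout: ",
                 paste(unique(bad), collapse = " ")))
  }
  with_seed(seed, {
    events <- list(); transcripts <- list(); clicks <- list()
    onsets <- numeric(0); n_typos <- 0L
    prompt_i <- 1L
    state <- speller_state(layout, prompts[[1]])
    state$suggestions <- suggest("", engine,
                                 n_words = slot_count(layout, "W"),
                                 n_letters = slot_count(layout, "L"))
    t_start <- 0
    t <- 0
    step <- 0L
    completed <- FALSE
    log_event <- function(t_ms, event, detail = "") {
      events[[length(events) + 1L]] <<- tibble(t_ms = t_ms, event = event,
                                               detail = as.character(detail))
    }
    while (step < max_steps) {
      step <- step + 1L
      state <- advance(state, layout, scan_cfg)
      h <- highlighted(state, layout, scan_cfg)
      step_end <- t + scan_cfg$step_ms
      # --- does the user intend to click during this step?
      tgt <- target_key(state, layout)
      wants <- FALSE
      if (h$kind == "row") {
        tgt_row <- key_row(layout, tgt)
        aim_row <- tgt_row
        if (user_cfg$error_rate > 0 && runif(1) < user_cfg$error_rate) {
          aim_row <- tgt_row %% length(layout$rows) + 1L   # aim at a wrong row
        }
        wants <- identical(h$row, aim_row)
      } else if (h$kind == "key") {
        aim_key <- tgt
        row_keys <- layout$rows[[state$sel_row]]
        if (!(tgt %in% row_keys)) {
          # wrong row was entered: select any key to escape, then fix it;
          # aim at the first key of the row
          aim_key <- row_keys[1]
        } else if (user_cfg$error_rate > 0 && runif(1) < user_cfg$error_rate) {
          ki <- match(tgt, row_keys)
          aim_key <- row_keys[ki %% length(row_keys) + 1L]
        }
        wants <- identical(h$key, aim_key)
      }
      if (wants) {
        onset <- t + runif(1, user_cfg$reaction_latency_ms[1],
                           user_cfg$reaction_latency_ms[2])
        onsets <- c(onsets, onset)
        log_event(onset, "grasp_onset", tgt)
        if (runif(1) < detector$sensitivity) {
          det <- onset + detector$detect_latency_ms
          osc <- det + detector$onscreen_delay_ms
          clicks[[length(clicks) + 1L]] <- tibble(detect_t_ms = det,
                                                  onscreen_t_ms = osc)
          if (osc <= step_end) {
            res <- apply_click(state, layout, scan_cfg, engine)
            state <- res$state
            log_event(osc, "click", res$action)
            if (!is.na(res$out_char)) {
              log_event(osc, "output", res$out_char)
              if (!is.na(state$pending_error)) {
                n_typos <- n_typos + nchar(res$out_char)
                log_event(osc, "typo", res$out_char)
              }
            }
            if (res$action == "ENTER" && state$typed == state$prompt) {
              transcripts[[prompt_i]] <- tibble(prompt = state$prompt,
                                                typed = state$typed,
                                                t_start_ms = t_start,
                                                t_end_ms = osc)
              log_event(osc, "sentence", state$typed)
              if (prompt_i == length(prompts)) { completed <- TRUE; t <- step_end; break }
              prompt_i <- prompt_i + 1L
              state <- speller_state(layout, prompts[[prompt_i]])
              state$suggestions <- suggest("", engine,
                                           n_words = slot_count(layout, "W"),
                                           n_letters = slot_count(layout, "L"))
              t_start <- osc
            }
          }
        }
      }
      # --- detector false positives, uniform over the step
      if (detector$fpf_per_min > 0 &&
          runif(1) < detector$fpf_per_min * scan_cfg$step_ms / 60000) {
        fp_det <- t + runif(1, 0, scan_cfg$step_ms)
        fp_osc <- fp_det + detector$onscreen_delay_ms
        clicks[[length(clicks) + 1L]] <- tibble(detect_t_ms = fp_det,
                                                onscreen_t_ms = fp_osc)
        res <- apply_click(state, layout, scan_cfg, engine)
        state <- res$state
        log_event(fp_osc, "click_fp", res$action)
        if (!is.na(res$out_char) && !is.na(state$pending_error)) {
          n_typos <- n_typos + nchar(res$out_char)
          log_event(fp_osc, "typo", res$out_char)
        }
      }
      t <- step_end
    }
    clicks <- if (length(clicks)) dplyr::bind_rows(clicks) else
      tibble(detect_t_ms = numeric(0), onscreen_t_ms = numeric(0))
    structure(list(
      events = if (length(events)) dplyr::bind_rows(events) else
        tibble(t_ms = numeric(0), event = character(0), detail = character(0)),
      transcripts = if (length(transcripts)) dplyr::bind_rows(transcripts) else
        tibble(prompt = character(0), typed = character(0),
               t_start_ms = numeric(0), t_end_ms = numeric(0)),
      clicks = clicks, grasp_onsets_ms = onsets,
      duration_min = t / 60000, n_typos = n_typos, completed = completed
    ), class = "session_log")
  })
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %.1f min, %d grasp onsets, %d clicks, %d/%d sentences%s\n",
              x$duration_min, length(x$grasp_onsets_ms), nrow(x$clicks),
              nrow(x$transcripts),
              nrow(x$transcripts) + !x$completed,
              if (x$completed) " (completed)" else ""))
  invisible(x)
}
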