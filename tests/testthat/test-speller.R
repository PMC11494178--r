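lay <- speller_layout()
scfg <- scan_config()

test_that("row scanning consumes three pre-selection steps before the first row", {
  st <- speller_state(lay, "a")
  for (i in 1:3) {
    st <- advance(st, lay, scfg)
    expect_equal(clickbci:::highlighted(st, lay, scfg)$kind, "none")
  }
  st <- advance(st, lay, scfg)                 # step 4: first actual row
  h <- clickbci:::highlighted(st, lay, scfg)
  expect_equal(h$kind, "row")
  expect_equal(h$row, 1L)
  # cyclic: one full cycle returns to the same highlight
  n_cycle <- 3 + length(lay$rows)
  st2 <- st
  for (i in seq_len(n_cycle)) st2 <- advance(st2, lay, scfg)
  expect_equal(clickbci:::highlighted(st2, lay, scfg),
               clickbci:::highlighted(st, lay, scfg))
})

test_that("column scanning has one pre-selection step and two clicks type a letter", {
  st <- speller_state(lay, "a")
  # advance to row 3 (letters a-f) and click it
  for (i in seq_len(3 + 3)) st <- advance(st, lay, scfg)
  res <- apply_click(st, lay, scfg)
  expect_equal(res$action, "row")
  st <- res$state
  expect_equal(st$phase, "col")
  st <- advance(st, lay, scfg)                 # pre-selection column
  expect_equal(clickbci:::highlighted(st, lay, scfg)$kind, "none")
  st <- advance(st, lay, scfg)                 # first key of the row
  h <- clickbci:::highlighted(st, lay, scfg)
  expect_equal(h$key, "a")
  res <- apply_click(st, lay, scfg)
  expect_equal(res$action, "a")
  expect_equal(res$state$typed, "a")
  expect_equal(res$state$phase, "row")         # cycle restarts
  expect_true(is.na(res$state$pending_error))  # correct character, no error
})

test_that("clicks during pre-selection steps are ignored", {
  st <- speller_state(lay, "a")
  st <- advance(st, lay, scfg)                 # pre-selection row 1
  res <- apply_click(st, lay, scfg)
  expect_equal(res$action, "none")
  expect_identical(res$state$typed, "")
})

test_that("wrong output sets the pending error and DEL clears it", {
  st <- speller_state(lay, "ab")
  st$typed <- "a"
  res <- clickbci:::execute_key(st, "x")       # wrong character
  expect_equal(res$state$pending_error, "char")
  expect_equal(res$state$typed, "ax")
  res2 <- clickbci:::execute_key(res$state, "DEL")
  expect_true(is.na(res2$state$pending_error))
  expect_equal(res2$state$typed, "a")
  # word-slot errors are cleared by A-DEL
  st2 <- speller_state(lay, "the canoe")
  st2$typed <- "the "
  st2$suggestions <- list(words = c("cat"), letters = character(0))
  res3 <- clickbci:::execute_key(st2, "W1")
  expect_equal(res3$state$pending_error, "word")
  res4 <- clickbci:::execute_key(res3$state, "A-DEL")
  expect_true(is.na(res4$state$pending_error))
  expect_equal(res4$state$typed, "the ")
})

test_that("the default suggestion engine is deterministic and truncates to slots", {
  eng <- default_suggest_engine()
  a <- suggest("th", eng)
  b <- suggest("th", eng)
  expect_identical(a, b)
  expect_lte(length(a$words), 4)
  expect_lte(length(a$letters), 4)
  expect_true(all(startsWith(a$words, "th")))
  expect_equal(a$words[1], "the")              # highest-frequency completion
  # empty context: most frequent word-initial suggestions
  e <- suggest("", eng)
  expect_equal(e$words[1], "the")
  # over-full engine output is truncated to the slot count
  big <- function(ctx) list(words = letters, letters = letters)
  expect_equal(length(suggest("x", big, n_words = 4)$words), 4)
  # engine failure degrades to empty suggestions
  boom <- function(ctx) stop("engine down")
  expect_equal(suggest("x", boom), list(words = character(0),
                                        letters = character(0)))
})

test_that("oracle detector and error-free user transcribe the prompt exactly", {
  prompt <- "the fish"
  log <- run_closed_loop(lay, scfg, user_config(), click_detector_sim(),
                         prompts = prompt, seed = 5)
  expect_true(log$completed)
  expect_equal(log$transcripts$typed, prompt)
  expect_equal(log$n_typos, 0)
  # click economy: 2 clicks per character plus 2 for ENTER
  expect_equal(nrow(log$clicks), 2 * (nchar(prompt) + 1))
  # every intent produced exactly one click (oracle sensitivity 1, no FPs)
  expect_equal(length(log$grasp_onsets_ms), nrow(log$clicks))
  # the session log supports the full metrics path
  perf <- evaluate_session(log)
  expect_equal(perf$value[perf$metric == "sensitivity"], 100)
  expect_equal(perf$value[perf$metric == "fpf"], 0)
})

test_that("closed-loop sessions are seed-deterministic", {
  a <- run_closed_loop(lay, scfg, user_config(error_rate = 0.1),
                       click_detector_sim(sensitivity = 0.9), "go on", seed = 11)
  b <- run_closed_loop(lay, scfg, user_config(error_rate = 0.1),
                       click_detector_sim(sensitivity = 0.9), "go on", seed = 11)
  expect_identical(a$events, b$events)
  expect_identical(a$clicks, b$clicks)
})

test_that("user errors lead to delete-key selections and sessions still finish", {
  log <- run_closed_loop(lay, scfg, user_config(error_rate = 0.25),
                         click_detector_sim(), prompts = "sat on", seed = 21,
                         max_steps = 3000)
  expect_true(log$completed)
  expect_equal(log$transcripts$typed, "sat on")
  dels <- log$events$detail[log$events$event == "click"]
  expect_true(any(dels %in% c("DEL", "A-DEL")))
  # mis-aimed clicks forced extra outputs beyond the prompt length
  n_outputs <- sum(log$events$event == "output")
  expect_gt(n_outputs, nchar("sat on"))
})

test_that("a detector with sensitivity below one still terminates via retries", {
  log <- run_closed_loop(lay, scfg, user_config(),
                         click_detector_sim(sensitivity = 0.7),
                         prompts = "we go", seed = 31, max_steps = 4000)
  expect_true(log$completed)
  expect_equal(log$transcripts$typed, "we go")
  # misses mean more intents than clicks
  expect_gt(length(log$grasp_onsets_ms), nrow(log$clicks))
})

test_that("prompts with characters missing from the layout are rejected", {
  expect_error(run_closed_loop(lay, scfg, user_config(), click_detector_sim(),
                               prompts = "q7z"), "absent")
})

test_that("board mode reuses the same machine with a 10-of-10 default", {
  board <- speller_layout(mode = "board")
  expect_equal(length(board$rows), 4)
  cfg10 <- voting_config(window = 10, threshold = 10)
  expect_equal(cfg10$threshold, 10L)
  st <- speller_state(board, "")
  for (i in 1:4) st <- advance(st, board, scfg)
  res <- apply_click(st, board, scfg)
  expect_equal(res$action, "row")
  st <- res$state
  for (i in 1:2) st <- advance(st, board, scfg)
  res <- apply_click(st, board, scfg)
  expect_equal(res$action, "icon01")
})

test_that("layout validation catches malformed grids", {
  expect_error(speller_layout(list(c("a", "a"))), "unique")
  expect_error(speller_layout(list(c("a", "b")), mode = "speller"), "DEL")
  expect_error(speller_layout(list(character(0))), "non-empty")
})
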