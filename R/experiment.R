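#' Experiment manifest
#'
#' Ties the pipeline stages into one reproducible end-to-end experiment. A
#' single global seed fans out to per-stage seeds by fixed offsets; the
#' manifest fingerprint stamps every output so re-runs are identifiable.
#'
#' @param seed Global seed.
#' @param mode `"standard"` (train a detector, evaluate it on simulated
#'   spelling sessions), `"training_sweep"` (models trained on nested trial
#'   subsets, each evaluated on the same held-out sessions), or
#'   `"model_update"` (retrain from harvested spelling data and compare
#'   against the fixed model).
#' @param synth_cfg A [synth_config()]; its defaults are the study conditions.
#' @param n_trials Cued training trials for the (largest) training set.
#' @param sweep_sizes Trial counts for the training-size sweep (nested
#'   subsets of the same session).
#' @param n_sessions Evaluation spelling sessions to simulate.
#' @param prompts Sentences per session.
#' @param voting_cfg A [voting_config()].
#' @param k Cross-validation folds used for fold construction.
#' @param epochs,calibration_s Model training epochs and calibration length
#'   (exposed so small experiments stay fast; defaults are the study values).
#' @param update_confound Logical: in `"model_update"` mode, add unmodeled
#'   low-frequency rest variability to the evaluation sessions.
#' @param out_dir Optional directory; reports and logs are written there as
#'   CSV/JSON.
#' @return An object of class `experiment_manifest`.
#' @export
experiment_manifest <- function(seed = 1, mode = c("standard", "training_sweep",
                                                   "model_update"),
                                synth_cfg = synth_config(),
                                n_trials = 40, sweep_sizes = NULL,
                                n_sessions = 3,
                                prompts = c("the birch canoe slid on the smooth planks"),
                                voting_cfg = voting_config(),
                                k = 10, epochs = 75, calibration_s = 60,
                                update_confound = TRUE,
                                out_dir = NULL) {
  mode <- match.arg(mode)
  structure(list(seed = as.integer(seed), mode = mode, synth_cfg = synth_cfg,
                 n_trials = n_trials, sweep_sizes = sweep_sizes,
                 n_sessions = n_sessions, prompts = prompts,
                 voting_cfg = voting_cfg, k = k, epochs = epochs,
                 calibration_s = calibration_s,
                 update_confound = update_confound, out_dir = out_dir,
                 version = as.character(utils::packageVersion("clickbci"))),
            class = "experiment_manifest")
}

# Cheap deterministic fingerprint of the manifest: a polynomial rolling hash
# over its deparsed representation, kept inside 31-bit integer range.
manifest_fingerprint <- function(manifest) {
  bytes <- utf8ToInt(paste(deparse(unclass(manifest)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Train a detector model from a cued training session: features, channel
# selection, shift warping, labeling (study onset/offset), folds, training on
# all retained samples.
train_pipeline <- function(synth_cfg, calib, n_trials, seed, k = 10,
                           epochs = 75, n_select = NULL, trials_use = NULL) {
  sess <- generate_training_session(synth_cfg, n_trials, seed = seed)
  frames <- stream_features(sess$recording, calib)
  cues <- sess$truth$cue_onset_ms
  if (!is.null(trials_use)) cues <- cues[seq_len(trials_use)]
  tt <- trial_tensor(frames, cues)
  if (is.null(n_select)) {
    n_select <- max(2L, min(length(synth_cfg$hand_channels), 12L))
  }
  chans <- select_modulated_channels(tt, n_select)
  warp <- fit_shift_warp(tt, channels = chans)
  # onset/offset of modulation estimated from the aligned trial average
  # (automated surrogate for the visual determination; an override can pin
  # study values instead)
  oo <- estimate_onset_offset(warp)
  labeled <- assign_labels(frames, cues, shifts = warp$shift_frames,
                           cfg = label_config(onset_s = oo[1], offset_s = oo[2],
                                              trial_window_s = c(-1, 2.5)))
  folded <- balance_and_fold(labeled, k = k, seed = child_seed(seed, 7))
  cfg <- model_config(input_dim = synth_cfg$n_channels, epochs = epochs,
                      seed = child_seed(seed, 11))
  seqs <- make_sequences(folded, cfg$seq_len)
  use <- which(folded$retained)
  use <- use[use %in% seqs$frame_row]
  sel <- match(use, seqs$frame_row)
  model <- build_model(cfg)
  model <- train_grasp_model(model, seqs$X[sel, , , drop = FALSE],
                             as.integer(folded$label[use]))
  list(model = model, folded = folded, warp = warp, channels = chans,
       truth = sess$truth, frames = frames, cfg = cfg)
}

# Simulate one spelling session against a trained model: closed loop with an
# oracle detector supplies the user's grasp onsets; a continuous recording is
# synthesized with bursts at those onsets; the full offline pipeline (features
# -> classifier -> voting) detects clicks; metrics come from aligning those
# clicks to the ground-truth onsets.
simulate_spelling_session <- function(model, calib, synth_cfg, voting_cfg,
                                      prompts, seed, confound = FALSE) {
  loop <- run_closed_loop(speller_layout(), scan_config(), user_config(),
                          click_detector_sim(), prompts, seed = seed)
  scfg <- synth_cfg
  if (confound) scfg$lf_confound <- lf_confound_default()
  rec <- generate_session_from_onsets(scfg, loop$grasp_onsets_ms,
                                      duration_ms = loop$duration_min * 60000,
                                      seed = child_seed(seed, 23))
  frames <- stream_features(rec, calib)
  clicks <- run_detector(model, frames, voting_cfg)
  al <- align_events(sort(loop$grasp_onsets_ms), clicks,
                     duration_min = loop$duration_min)
  list(loop = loop, clicks = clicks, alignment = al,
       sensitivity = click_sensitivity(al), rates = click_rates(al),
       frames = frames)
}

#' Run an end-to-end experiment
#'
#' Executes the manifest's mode deterministically given its seed and returns
#' (and optionally writes) the resulting reports. See
#' [experiment_manifest()] for the modes.
#'
#' @param manifest An [experiment_manifest()].
#' @return An object of class `experiment_result`: list with `report` (a
#'   tibble of metrics), `fingerprint`, `mode`, and mode-specific extras
#'   (`comparison` for sweep/update modes).
#' @export
run_experiment <- function(manifest) {
  stopifnot(inherits(manifest, "experiment_manifest"))
  fp <- manifest_fingerprint(manifest)
  seed <- manifest$seed
  scfg <- manifest$synth_cfg
  calib_rec <- generate_calibration(scfg, manifest$calibration_s,
                                    seed = child_seed(seed, 1))
  calib <- fit_calibration(calib_rec)
  report <- NULL; comparison <- NULL; extras <- list()

  if (manifest$mode == "standard") {
    tp <- train_pipeline(scfg, calib, manifest$n_trials,
                         seed = child_seed(seed, 2), k = manifest$k,
                         epochs = manifest$epochs)
    rows <- list()
    for (s in seq_len(manifest$n_sessions)) {
      sim <- simulate_spelling_session(tp$model, calib, scfg,
                                       manifest$voting_cfg, manifest$prompts,
                                       seed = child_seed(seed, 100 + s))
      rows[[s]] <- tibble(session = s, sensitivity = sim$sensitivity,
                          tpf_per_min = sim$rates$tpf_per_min,
                          fpf_per_min = sim$rates$fpf_per_min)
    }
    report <- dplyr::bind_rows(rows)
    extras$model <- tp$model
  } else if (manifest$mode == "training_sweep") {
    sizes <- manifest$sweep_sizes
    if (is.null(sizes)) sizes <- unique(round(manifest$n_trials * c(0.25, 0.5, 1)))
    sess_seed <- child_seed(seed, 2)
    rows <- list()
    per_size <- list()
    for (sz in sizes) {
      tp <- train_pipeline(scfg, calib, manifest$n_trials, seed = sess_seed,
                           k = manifest$k, epochs = manifest$epochs,
                           trials_use = sz)
      sens <- vapply(seq_len(manifest$n_sessions), function(s) {
        sim <- simulate_spelling_session(tp$model, calib, scfg,
                                         manifest$voting_cfg, manifest$prompts,
                                         seed = child_seed(seed, 100 + s))
        sim$sensitivity
      }, numeric(1))
      per_size[[as.character(sz)]] <- sens
      rows[[length(rows) + 1]] <- tibble(n_trials = sz,
                                         median_sensitivity = median(sens))
    }
    report <- dplyr::bind_rows(rows)
    comparison <- compare_groups(list(
      smallest_vs_largest = list(per_size[[1]], per_size[[length(per_size)]])))
    extras$per_size <- per_size
  } else { # model_update
    tp <- train_pipeline(scfg, calib, manifest$n_trials,
                         seed = child_seed(seed, 2), k = manifest$k,
                         epochs = manifest$epochs)
    # collect spelling blocks with the fixed model, harvest labels from their
    # ground-truth onsets, retrain
    sim0 <- simulate_spelling_session(tp$model, calib, scfg,
                                      manifest$voting_cfg, manifest$prompts,
                                      seed = child_seed(seed, 200),
                                      confound = manifest$update_confound)
    harvest <- harvest_training_from_spelling(sim0$frames,
                                              sort(sim0$loop$grasp_onsets_ms))
    lab <- harvest$labeled[!is.na(harvest$labeled$label), ]
    folded <- balance_and_fold(lab, k = min(manifest$k, sum(lab$label == "grasp")),
                               seed = child_seed(seed, 31))
    cfg <- tp$cfg
    seqs <- make_sequences(folded, cfg$seq_len)
    use <- which(folded$retained); use <- use[use %in% seqs$frame_row]
    sel <- match(use, seqs$frame_row)
    upd <- build_model(model_config(input_dim = scfg$n_channels,
                                    epochs = manifest$epochs,
                                    seed = child_seed(seed, 37)))
    upd <- train_grasp_model(upd, seqs$X[sel, , , drop = FALSE],
                             as.integer(folded$label[use]))
    fixed_fpf <- numeric(0); upd_fpf <- numeric(0); rows <- list()
    for (s in seq_len(manifest$n_sessions)) {
      simf <- simulate_spelling_session(tp$model, calib, scfg,
                                        manifest$voting_cfg, manifest$prompts,
                                        seed = child_seed(seed, 300 + s),
                                        confound = manifest$update_confound)
      simu <- simulate_spelling_session(upd, calib, scfg,
                                        manifest$voting_cfg, manifest$prompts,
                                        seed = child_seed(seed, 300 + s),
                                        confound = manifest$update_confound)
      fixed_fpf <- c(fixed_fpf, simf$rates$fpf_per_min)
      upd_fpf <- c(upd_fpf, simu$rates$fpf_per_min)
      rows[[s]] <- tibble(session = s,
                          model = c("fixed", "updated"),
                          sensitivity = c(simf$sensitivity, simu$sensitivity),
                          fpf_per_min = c(simf$rates$fpf_per_min,
                                          simu$rates$fpf_per_min))
    }
    report <- dplyr::bind_rows(rows)
    comparison <- compare_groups(list(fpf_fixed_vs_updated =
                                        list(fixed_fpf, upd_fpf)))
    extras$updated_model <- upd
    extras$fixed_model <- tp$model
  }

  res <- structure(c(list(report = report, comparison = comparison,
                          fingerprint = fp, mode = manifest$mode,
                          manifest = manifest), extras),
                   class = "experiment_result")
  if (!is.null(manifest$out_dir)) {
    dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(manifest$out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(fingerprint = fp, mode = manifest$mode,
                              seed = manifest$seed,
                              version = manifest$version),
                         file.path(manifest$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> mode=%s fingerprint=%s\n", x$mode,
              x$fingerprint))
  print(x$report)
  invisible(x)
}
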