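# Plain-text serialization: recordings as CSV plus a JSON sidecar carrying
# the sampling rate and channel names; calibration statistics as a single
# JSON document; session logs as CSV events plus a JSON summary.

#' Write / read a recording as CSV + JSON sidecar
#'
#' The CSV holds one row per sample and one column per channel; the sidecar
#' (`<path>.json`) documents `fs_hz`, `n_channels`, `n_samples` and channel
#' names, so the container is self-describing.
#'
#' @param recording An [ecog_recording()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `path`, invisibly (writer); an [ecog_recording()] (reader).
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "ecog_recording"))
  utils::write.csv(as.data.frame(recording$signal), path, row.names = FALSE)
  meta <- list(fs_hz = recording$fs_hz,
               n_channels = ncol(recording$signal),
               n_samples = nrow(recording$signal),
               channels = colnames(recording$signal))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sig <- as.matrix(utils::read.csv(path))
  if (nrow(sig) != meta$n_samples || ncol(sig) != meta$n_channels) {
    abort("recording CSV does not match its sidecar metadata")
  }
  ecog_recording(sig, meta$fs_hz)
}

#' Write / read calibration statistics as JSON
#'
#' @param calib A [fit_calibration()] result.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `bci_calibration` (reader).
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "bci_calibration"))
  cfg <- calib$cfg
  doc <- list(mean = calib$mean, sd = calib$sd,
              band_mean = calib$band_mean, band_sd = calib$band_sd,
              n_frames = calib$n_frames,
              cfg = cfg[c("fs_hz", "window_ms", "step_ms", "hg_low_hz",
                          "hg_high_hz", "taper", "normalization", "sd_floor")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(spectral_config, doc$cfg)
  structure(list(mean = doc$mean, sd = doc$sd, band_mean = doc$band_mean,
                 band_sd = doc$band_sd, n_frames = doc$n_frames, cfg = cfg),
            class = "bci_calibration")
}

#' Write a closed-loop session log as CSV events + JSON summary
#'
#' @param session A `session_log` from [run_closed_loop()].
#' @param path CSV file path for the event table; the summary goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  stopifnot(inherits(session, "session_log"))
  utils::write.csv(session$events, path, row.names = FALSE)
  jsonlite::write_json(
    list(duration_min = session$duration_min,
         n_grasp_onsets = length(session$grasp_onsets_ms),
         n_clicks = nrow(session$clicks),
         n_typos = session$n_typos,
         completed = session$completed,
         transcripts = session$transcripts),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize / restore a trained model as JSON
#'
#' A documented, versioned plain-text container: config, flattened weight
#' matrices with shapes, and training history. A reloaded model reproduces
#' outputs bit-for-bit.
#'
#' @param model A `grasp_model`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `grasp_model` (reader).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "grasp_model"))
  # weights are stored as %.17g strings: 17 significant digits round-trip
  # IEEE doubles exactly, so a reloaded model reproduces outputs bit-for-bit
  doc <- list(
    format = "clickbci-model", version = 1L,
    cfg = unclass(model$cfg), trained = model$trained,
    history = model$history,
    params = lapply(model$params, function(m) {
      if (is.matrix(m)) list(dim = dim(m), data = sprintf("%.17g", as.numeric(m)))
      else list(dim = length(m), data = sprintf("%.17g", as.numeric(m)))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "clickbci-model") || doc$version != 1) {
    abort("not a clickbci model file (or unsupported version)")
  }
  params <- lapply(doc$params, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) == 2) matrix(v, p$dim[1], p$dim[2]) else v
  })
  cfg <- do.call(model_config, doc$cfg[c("input_dim", "seq_len", "lstm_units",
                                         "fc1_units", "dropout", "epochs",
                                         "batch_size", "learning_rate", "seed")])
  structure(list(params = params, cfg = cfg, trained = doc$trained,
                 history = as_tibble(doc$history)),
            class = "grasp_model")
}
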