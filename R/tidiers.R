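# broom-style tidiers for the package's fitted objects.

#' Tidy a trained grasp classifier
#'
#' @param x A `grasp_model`.
#' @param ... Unused.
#' @return Per-epoch training history: `epoch`, `loss`, `accuracy`.
#' @export
tidy.grasp_model <- function(x, ...) x$history

#' One-row summary of a grasp classifier
#'
#' @param x A `grasp_model`.
#' @param ... Unused.
#' @return A tibble: architecture sizes, parameter count, final loss.
#' @export
glance.grasp_model <- function(x, ...) {
  tibble(input_dim = x$cfg$input_dim, seq_len = x$cfg$seq_len,
         lstm_units = x$cfg$lstm_units, fc1_units = x$cfg$fc1_units,
         n_parameters = n_parameters(x), trained = x$trained,
         final_loss = if (nrow(x$history)) tail(x$history$loss, 1) else NA_real_,
         final_accuracy = if (nrow(x$history)) tail(x$history$accuracy, 1) else NA_real_)
}

#' Tidy cross-validation results
#'
#' @param x A `bci_cv`.
#' @param ... Unused.
#' @return Per-fold, per-repetition accuracies.
#' @export
tidy.bci_cv <- function(x, ...) x$accuracy

#' One-row summary of cross-validation results
#'
#' @param x A `bci_cv`.
#' @param ... Unused.
#' @return A tibble: mean/sd accuracy, fold and repetition counts, pooled
#'   confusion counts.
#' @export
glance.bci_cv <- function(x, ...) {
  cm <- x$confusion
  tibble(mean_accuracy = mean(x$accuracy$accuracy),
         sd_accuracy = sd(x$accuracy$accuracy),
         k = length(unique(x$accuracy$fold)),
         reps = max(x$accuracy$rep),
         pooled_accuracy = sum(diag(cm)) / sum(cm))
}

#' Tidy an event alignment
#'
#' @param x An `event_alignment`.
#' @param ... Unused.
#' @return One row per matched grasp with latencies in ms.
#' @export
tidy.event_alignment <- function(x, ...) {
  dplyr::mutate(x$matches,
                detect_latency_ms = .data$detect_t_ms - .data$grasp_onset_ms,
                onscreen_latency_ms = .data$onscreen_t_ms - .data$grasp_onset_ms)
}

#' One-row summary of an event alignment
#'
#' @param x An `event_alignment`.
#' @param ... Unused.
#' @return Counts, sensitivity and rates.
#' @export
glance.event_alignment <- function(x, ...) {
  r <- click_rates(x)
  tibble(n_grasps = x$n_grasps, n_tp = x$n_tp, n_fp = x$n_fp, n_fn = x$n_fn,
         sensitivity = click_sensitivity(x),
         tpf_per_min = r$tpf_per_min, fpf_per_min = r$fpf_per_min)
}
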