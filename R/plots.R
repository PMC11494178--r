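# ggplot2 displays for the package's result types.

#' Plot channel saliency
#'
#' @param object A `bci_saliency` from [saliency_map()].
#' @param ... Unused.
#' @return A ggplot: per-channel normalized saliency.
#' @export
autoplot.bci_saliency <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$channel, y = .data$saliency)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "channel", y = "saliency (0-1)",
                  title = "Integrated-gradients channel saliency") +
    ggplot2::theme_minimal()
}

#' Plot session performance metrics
#'
#' @param object A `bci_performance` from [evaluate_session()].
#' @param ... Unused.
#' @return A ggplot: one point per metric, faceted by unit.
#' @export
autoplot.bci_performance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~unit, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Session performance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot cross-validation accuracies
#'
#' @param object A `bci_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot: per-fold accuracies with the chance level marked.
#' @export
autoplot.bci_cv <- function(object, ...) {
  ggplot2::ggplot(object$accuracy,
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "validation accuracy",
                  title = "Cross-validated classification accuracy") +
    ggplot2::theme_minimal()
}

#' Plot the aligned trial-average high-gamma template
#'
#' @param warp A `shift_warp` from [fit_shift_warp()].
#' @return A ggplot: template traces of the fitted channels against trial
#'   time.
#' @export
plot_warp_template <- function(warp) {
  tmpl <- warp$template
  colnames(tmpl) <- paste0("ch", warp$channels_used)
  df <- as_tibble(tmpl)
  df$rel_t_s <- warp$rel_t_ms / 1000
  long <- tidyr::pivot_longer(df, -"rel_t_s", names_to = "channel",
                              values_to = "hg")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rel_t_s, y = .data$hg,
                                     color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time from cue (s)", y = "high-gamma (z-sum)",
                  title = "Aligned trial-average template") +
    ggplot2::theme_minimal()
}
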