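# Gradient of the chosen scalar output with respect to the input sequence.
# target "logit": pre-softmax grasp score; "prob": softmax grasp probability.
input_gradient <- function(model, X, target = c("logit", "prob")) {
  target <- match.arg(target)
  fw <- lstm_forward(model$params, X, keep_cache = TRUE)
  n <- dim(X)[1]
  dlogits <- if (target == "logit") {
    matrix(rep(c(0, 1), each = n), n)
  } else {
    p <- fw$probs
    # d p_grasp / d logits = p2 * (delta_k2 - p_k)
    cbind(-p[, 2] * p[, 1], p[, 2] * (1 - p[, 2]))
  }
  bw <- lstm_backward(model$params, X, fw, dlogits, want_dX = TRUE)
  list(dX = bw$dX, fw = fw)
}

# Scalar output value used by integrated gradients.
target_value <- function(model, X, target) {
  fw <- lstm_forward(model$params, X)
  if (target == "logit") fw$logits[, 2] else fw$probs[, 2]
}

# Generic trapezoid-rule path attribution: f_grad(X) takes a batch array of
# inputs (n x ...) and returns gradients of a scalar output per input, same
# shape. Shared by the model-specific wrapper and usable with any
# differentiable map (e.g. a linear model, for which the result is exact).
ig_path_attributions <- function(f_grad, sample, baseline, steps) {
  diffm <- sample - baseline
  alphas <- seq(0, 1, length.out = steps + 1)
  X <- array(0, c(steps + 1, nrow(sample), ncol(sample)))
  for (i in seq_along(alphas)) X[i, , ] <- baseline + alphas[i] * diffm
  g <- f_grad(X)
  wts <- c(0.5, rep(1, steps - 1), 0.5) / steps
  avg_grad <- matrix(0, nrow(sample), ncol(sample))
  for (i in seq_along(alphas)) {
    avg_grad <- avg_grad + wts[i] * matrix(g[i, , ], nrow(sample))
  }
  diffm * avg_grad
}

#' Integrated-gradients attribution of a grasp classification
#'
#' Path-integral attribution of the grasp-class output to each element of the
#' input feature history, approximated by a trapezoid rule over `steps`
#' points on the straight line from the baseline to the sample. Satisfies the
#' completeness axiom: the attributions sum to
#' `F(sample) - F(baseline)` up to quadrature error.
#'
#' The default baseline is the all-zero feature history — for z-scored
#' high-gamma features, zero is the rest-state expectation. The default
#' attribution target is the grasp-class pre-softmax score.
#'
#' @param model A trained `grasp_model`.
#' @param sample A `seq_len x channels` matrix (one input sequence).
#' @param baseline Same shape as `sample`; default all zeros.
#' @param steps Number of path points (>= 1; default 64).
#' @param target `"logit"` (default) or `"prob"`.
#' @return An object of class `attribution_map`: list with `attributions`
#'   (`seq_len x channels`), `completeness_gap` (absolute difference between
#'   the attribution sum and `F(sample) - F(baseline)`), `steps`, `target`.
#' @export
integrated_gradients <- function(model, sample, baseline = NULL, steps = 64,
                                 target = c("logit", "prob")) {
  target <- match.arg(target)
  if (steps < 1) abort("steps must be >= 1")
  sample <- as.matrix(sample)
  if (!all(dim(sample) == c(model$cfg$seq_len, model$cfg$input_dim))) {
    abort("sample shape must be seq_len x input_dim")
  }
  if (is.null(baseline)) baseline <- matrix(0, nrow(sample), ncol(sample))
  attr_map <- ig_path_attributions(
    function(X) input_gradient(model, X, target)$dX,
    sample, baseline, steps)
  Xe <- array(0, c(2, nrow(sample), ncol(sample)))
  Xe[1, , ] <- baseline; Xe[2, , ] <- sample
  ends <- target_value(model, Xe, target)
  gap <- abs(sum(attr_map) - (ends[2] - ends[1]))
  structure(list(attributions = attr_map, completeness_gap = gap,
                 steps = steps, target = target),
            class = "attribution_map")
}

#' Channel saliency from cross-validated models
#'
#' For every grasp-labeled validation sample of every cross-validated model
#' (optionally across repeated retrainings), computes the integrated-gradients
#' attribution map, takes the L2 norm across the time (history) axis to get a
#' per-channel value, averages over all samples, models and repetitions, and
#' min-max normalizes the result to `[0, 1]`.
#'
#' @param cv A [cross_validate()] result (its kept fold models and validation
#'   samples are used), or a list of such results (one per repetition).
#' @param steps Integrated-gradients path points per sample (default 16 —
#'   saliency averages thousands of maps, so few points suffice; raise for
#'   tighter completeness).
#' @param target Attribution target, `"logit"` or `"prob"`.
#' @param max_samples_per_fold Optional cap on grasp samples per fold for
#'   speed.
#' @return An object of class `bci_saliency`: tibble with `channel`,
#'   `saliency` (in `[0, 1]`, max 1), `raw` (pre-normalization mean).
#' @export
saliency_map <- function(cv, steps = 16, target = c("logit", "prob"),
                         max_samples_per_fold = Inf) {
  target <- match.arg(target)
  reps <- if (inherits(cv, "bci_cv")) list(cv) else cv
  d <- reps[[1]]$cfg$input_dim
  acc <- numeric(d); n_maps <- 0L
  for (r in reps) {
    for (fi in seq_along(r$models)) {
      m <- r$models[[fi]]
      vs <- r$val_samples[[fi]]
      grasp_rows <- vs$rows[r$labels[vs$rows] == 2L]
      if (!length(grasp_rows)) next
      if (length(grasp_rows) > max_samples_per_fold) {
        grasp_rows <- grasp_rows[seq_len(max_samples_per_fold)]
      }
      sel <- match(grasp_rows, r$sequences$frame_row)
      for (s in sel) {
        ig <- integrated_gradients(m, matrix(r$sequences$X[s, , ], m$cfg$seq_len),
                                   steps = steps, target = target)
        acc <- acc + sqrt(colSums(ig$attributions^2))
        n_maps <- n_maps + 1L
      }
    }
  }
  if (n_maps == 0) abort("no grasp-labeled validation samples")
  raw <- acc / n_maps
  rng <- range(raw)
  sal <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else rep(0, d)
  structure(tibble(channel = seq_len(d), saliency = sal, raw = raw),
            class = c("bci_saliency", "tbl_df", "tbl", "data.frame"))
}
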