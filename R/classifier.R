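#' Grasp classifier configuration
#'
#' Many-to-one recurrent network mapping 1 s of feature history (10 frames at
#' the 100 ms cadence) to rest/grasp probabilities: an LSTM layer with 25
#' hidden units, a fully-connected layer with 10 units (eLU activation), and
#' a 2-unit softmax output. Training uses categorical cross-entropy, Adam,
#' 45-sample batches, 75 epochs, 30% dropout on the LSTM and FC1 outputs, and
#' He-normal initialization of all weight matrices (including recurrent ones).
#'
#' Under the standard single-bias LSTM parameterization this network has
#' `4*((d+25)*25+25) + (25*10+10) + (10*2+2)` trainable parameters — 15,682
#' for d = 128 input channels (see [n_parameters()]).
#'
#' @param input_dim Number of input channels.
#' @param seq_len Frames of history per sequence (default 10 = 1 s).
#' @param lstm_units,fc1_units Layer sizes.
#' @param dropout Dropout fraction in `[0, 1)`, applied to the LSTM output and
#'   the FC1 output during training (not to recurrent connections).
#' @param epochs,batch_size,learning_rate Training hyperparameters. The
#'   learning rate is the Adam default `1e-3`.
#' @param seed Seed governing initialization, shuffling, and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_dim, seq_len = 10, lstm_units = 25,
                         fc1_units = 10, dropout = 0.30, epochs = 75,
                         batch_size = 45, learning_rate = 1e-3, seed = 1) {
  stopifnot_scalar_number(input_dim, "input_dim", 1)
  stopifnot_scalar_number(seq_len, "seq_len", 1)
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 seq_len = as.integer(seq_len),
                 lstm_units = as.integer(lstm_units),
                 fc1_units = as.integer(fc1_units),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "model_config")
}

#' Build an untrained grasp classifier
#'
#' Initializes all weight matrices from a He-normal distribution (biases
#' zero), deterministically given the config seed.
#'
#' @param cfg A [model_config()].
#' @return An object of class `grasp_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  params <- with_seed(cfg$seed,
                      lstm_init(cfg$input_dim, cfg$lstm_units, cfg$fc1_units))
  structure(list(params = params, cfg = cfg, trained = FALSE,
                 history = tibble(epoch = integer(), loss = numeric(),
                                  accuracy = numeric())),
            class = "grasp_model")
}

#' Number of trainable parameters
#' @param model A [build_model()] result.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) lstm_n_params(model$params)

#' @export
print.grasp_model <- function(x, ...) {
  cat(sprintf("<grasp_model> %d-ch x %d-frame input, LSTM(%d)-FC(%d)-FC(2), %d parameters, %s\n",
              x$cfg$input_dim, x$cfg$seq_len, x$cfg$lstm_units,
              x$cfg$fc1_units, n_parameters(x),
              if (x$trained) sprintf("trained (%d epochs)", max(x$history$epoch))
              else "untrained"))
  invisible(x)
}

#' Build input sequences from a feature stream
#'
#' Sequence i ends at frame i and spans the preceding `seq_len` frames; only
#' frames with a full history are returned.
#'
#' @param frames Feature tibble.
#' @param seq_len History length in frames.
#' @return List: `X` (n x seq_len x channels array), `frame_row` (row index
#'   into `frames` of each sequence's final frame).
#' @export
make_sequences <- function(frames, seq_len = 10) {
  mat <- feature_matrix(frames)
  n <- nrow(mat)
  if (n < seq_len) abort("need at least seq_len frames")
  rows <- seq_len:n
  X <- array(NA_real_, c(length(rows), seq_len, ncol(mat)))
  for (k in seq_len(seq_len)) {
    X[, k, ] <- mat[rows - seq_len + k, , drop = FALSE]
  }
  list(X = X, frame_row = rows)
}

#' Train the grasp classifier
#'
#' Mini-batch training with categorical cross-entropy loss, Adam updates, and
#' inverted dropout; per-epoch loss and training accuracy are recorded in the
#' model history. Reproducible given the seed.
#'
#' @param model A [build_model()] result.
#' @param X n x seq_len x channels array of input sequences.
#' @param y Labels: factor with levels rest/grasp, or integers (1 = rest,
#'   2 = grasp).
#' @param seed Seed for shuffling and dropout; defaults to the config seed.
#' @return The trained `grasp_model`.
#' @export
train_grasp_model <- function(model, X, y, seed = model$cfg$seed) {
  cfg <- model$cfg
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (!all(y %in% c(1L, 2L))) abort("labels must be 1 (rest) or 2 (grasp)")
  if (length(unique(y)) < 2) abort("both classes must be present for training")
  n <- dim(X)[1]
  Y <- matrix(0, n, 2); Y[cbind(seq_len(n), y)] <- 1
  p <- model$params
  opt <- adam_init(p)
  hist <- vector("list", cfg$epochs)
  keep <- 1 - cfg$dropout
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
        Xb <- X[idx, , , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        nb <- length(idx)
        dh <- if (cfg$dropout > 0) {
          matrix(stats::rbinom(nb * cfg$lstm_units, 1, keep), nb) / keep
        }
        df <- if (cfg$dropout > 0) {
          matrix(stats::rbinom(nb * cfg$fc1_units, 1, keep), nb) / keep
        }
        fw <- lstm_forward(p, Xb, drop_h = dh, drop_f = df, keep_cache = TRUE)
        eps <- 1e-12
        tot_loss <- tot_loss - sum(Yb * log(fw$probs + eps))
        tot_correct <- tot_correct +
          sum(max.col(fw$probs) == max.col(Yb))
        dlogits <- (fw$probs - Yb) / nb
        bw <- lstm_backward(p, Xb, fw, dlogits)
        upd <- adam_step(p, bw$grads, opt, lr = cfg$learning_rate)
        p <- upd$params; opt <- upd$state
      }
      hist[[ep]] <- tibble(epoch = ep, loss = tot_loss / n,
                           accuracy = tot_correct / n)
    }
  })
  model$params <- p
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Classify a feature stream
#'
#' One prediction per frame at the 100 ms cadence once the history buffer is
#' full; the first `seq_len - 1` warm-up frames emit rest by convention (with
#' `p_grasp = NA`). Batch and streaming evaluation of the same frames are
#' identical because the forward pass is deterministic.
#'
#' @param model A trained `grasp_model`.
#' @param frames Feature tibble.
#' @return A tibble: `t_ms`, `label` (factor rest/grasp), `p_grasp`.
#' @export
predict_stream <- function(model, frames) {
  mat <- feature_matrix(frames)
  if (ncol(mat) != model$cfg$input_dim) {
    abort(sprintf("model expects %d channels, got %d",
                  model$cfg$input_dim, ncol(mat)))
  }
  seqs <- make_sequences(frames, model$cfg$seq_len)
  fw <- lstm_forward(model$params, seqs$X)
  p_grasp <- rep(NA_real_, nrow(mat))
  p_grasp[seqs$frame_row] <- fw$probs[, 2]
  label <- rep("rest", nrow(mat))
  label[seqs$frame_row] <- c("rest", "grasp")[max.col(fw$probs)]
  tibble(t_ms = frames$t_ms,
         label = factor(label, levels = c("rest", "grasp")),
         p_grasp = p_grasp)
}

#' Cross-validate the classifier on balanced contiguous folds
#'
#' Each fold is used once for validation while a model is trained on the
#' remaining folds; optionally the whole procedure is repeated with fresh
#' initializations to average over training stochasticity. Returns per-fold
#' accuracies and the pooled confusion matrix over all validation
#' predictions. The fitted per-fold models of the final repetition are kept
#' for downstream attribution analysis.
#'
#' @param folded Output of [balance_and_fold()].
#' @param cfg A [model_config()].
#' @param reps Number of training repetitions (default 1).
#' @param seed Base seed; per-fold, per-rep seeds are derived from it.
#' @return An object of class `bci_cv`: list with `accuracy` (tibble: rep,
#'   fold, accuracy, n), `confusion` (2 x 2 matrix, rows = truth), `models`
#'   (list of fold models from the last rep), `cfg`.
#' @export
cross_validate <- function(folded, cfg, reps = 1, seed = cfg$seed) {
  stopifnot(all(c("fold", "retained", "label") %in% names(folded)))
  seqs <- make_sequences(folded, cfg$seq_len)
  y_all <- as.integer(folded$label)
  usable <- rep(FALSE, nrow(folded))
  usable[seqs$frame_row] <- TRUE
  folds <- sort(unique(folded$fold))
  acc <- list(); conf <- matrix(0, 2, 2,
                                dimnames = list(truth = c("rest", "grasp"),
                                                pred = c("rest", "grasp")))
  models <- vector("list", length(folds))
  samples <- vector("list", length(folds))
  for (r in seq_len(reps)) {
    for (fi in seq_along(folds)) {
      f <- folds[fi]
      tr_rows <- which(folded$retained & usable & folded$fold != f)
      va_rows <- which(folded$retained & usable & folded$fold == f)
      if (length(va_rows) == 0 || length(unique(y_all[tr_rows])) < 2) {
        abort("degenerate fold: missing class or empty validation set")
      }
      sel_tr <- match(tr_rows, seqs$frame_row)
      sel_va <- match(va_rows, seqs$frame_row)
      m <- build_model(model_config(
        input_dim = cfg$input_dim, seq_len = cfg$seq_len,
        lstm_units = cfg$lstm_units, fc1_units = cfg$fc1_units,
        dropout = cfg$dropout, epochs = cfg$epochs,
        batch_size = cfg$batch_size, learning_rate = cfg$learning_rate,
        seed = child_seed(seed, r * 100 + fi)))
      m <- train_grasp_model(m, seqs$X[sel_tr, , , drop = FALSE], y_all[tr_rows])
      fw <- lstm_forward(m$params, seqs$X[sel_va, , , drop = FALSE])
      pred <- max.col(fw$probs)
      truth <- y_all[va_rows]
      acc[[length(acc) + 1]] <- tibble(rep = r, fold = f,
                                       accuracy = mean(pred == truth),
                                       n = length(truth))
      for (i in 1:2) for (j in 1:2) {
        conf[i, j] <- conf[i, j] + sum(truth == i & pred == j)
      }
      if (r == reps) {
        models[[fi]] <- m
        samples[[fi]] <- list(rows = va_rows, seq_idx = sel_va)
      }
    }
  }
  structure(list(accuracy = dplyr::bind_rows(acc), confusion = conf,
                 models = models, val_samples = samples,
                 sequences = seqs, labels = y_all, cfg = cfg),
            class = "bci_cv")
}

#' @export
print.bci_cv <- function(x, ...) {
  cat(sprintf("<bci_cv> %d folds x %d reps, mean accuracy %.3f\n",
              length(unique(x$accuracy$fold)), max(x$accuracy$rep),
              mean(x$accuracy$accuracy)))
  invisible(x)
}
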