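# Internal helpers shared across modules.

# Evaluate `expr` under a locally seeded RNG without disturbing the caller's
# RNG state. All user-facing stochastic operations funnel through this so that
# a given seed is reproducible regardless of surrounding code.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

# Derive a child seed from a parent seed and a stage offset, staying inside
# 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 2654435761 + offset * 97) %% 2147483647L) + 1L
}

#' Channel column names used in feature tibbles
#'
#' Feature frames are tibbles with one column per channel; columns are named
#' `ch001`, `ch002`, ... so they sort naturally and round-trip through CSV.
#'
#' @param n Number of channels, or a character vector to validate.
#' @return Character vector of channel column names.
#' @keywords internal
channel_names <- function(n) {
  sprintf("ch%03d", seq_len(n))
}

# Extract the channel-value matrix (frames x channels) from a feature tibble.
feature_matrix <- function(frames) {
  cols <- grep("^ch\\d+$", names(frames), value = TRUE)
  if (length(cols) == 0) abort("no channel columns (ch###) found in frames")
  as.matrix(frames[, cols, drop = FALSE])
}

# Build a feature tibble from a timestamp vector and frames x channels matrix.
feature_tibble <- function(t_ms, mat, extra = NULL) {
  colnames(mat) <- channel_names(ncol(mat))
  out <- dplyr::bind_cols(tibble(t_ms = t_ms), as_tibble(mat))
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower) {
    abort(sprintf("`%s` must be a finite scalar >= %s", name, lower))
  }
  invisible(x)
}
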