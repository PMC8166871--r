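#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scoring model into its per-position weights
#'
#' @param x A [lir_model()].
#' @param matrix Also return the 300 unique substitution entries (long
#'   format) instead of the position weights.
#' @param ... Unused.
#' @return With `matrix = FALSE` (default), a tibble with one row per window
#'   position: `position` (1-18), `offset` (-7..+10 relative to the aromatic
#'   anchor), `weight`. With `matrix = TRUE`, columns `a`, `b`, `value`.
#' @export
tidy.lir_model <- function(x, matrix = FALSE, ...) {
  if (matrix) {
    pairs <- matrix_pairs()
    ab <- lir_alphabet()
    return(tibble::tibble(a = ab[pairs[, 1]], b = ab[pairs[, 2]],
                          value = x$matrix[pairs]))
  }
  tibble::tibble(position = seq_len(WINDOW_LEN),
                 offset = seq_len(WINDOW_LEN) - ANCHOR0_IDX,
                 weight = x$weights)
}

#' One-row summary of a scoring model
#'
#' @param x A [lir_model()].
#' @param ... Unused.
#' @return Tibble with `origin`, `n_reference`, `n_zero_weights`,
#'   `n_zero_entries`, `seed`.
#' @export
glance.lir_model <- function(x, ...) {
  pairs <- matrix_pairs()
  tibble::tibble(origin = x$origin,
                 n_reference = nrow(x$reference),
                 n_zero_weights = sum(x$weights == 0),
                 n_zero_entries = sum(x$matrix[pairs] == 0),
                 seed = x$seed %||% NA_integer_)
}

#' Tidy a training result into its acceptance trace
#'
#' @param x The list returned by [train_lir_model()].
#' @param ... Unused.
#' @return The `trace` tibble (one row per accepted proposal).
#' @export
tidy.lir_training <- function(x, ...) x$trace

#' One-row summary of a training run
#'
#' @param x The list returned by [train_lir_model()].
#' @param ... Unused.
#' @return Tibble with `initial_auc`, `final_auc`, `n_accepted`.
#' @export
glance.lir_training <- function(x, ...) {
  tibble::tibble(initial_auc = x$initial_auc, final_auc = x$final_auc,
                 n_accepted = nrow(x$trace))
}
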