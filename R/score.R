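# The similarity scorer: a query window's score is the average, over the N
# reference (positive) windows, of the position-weighted substitution
# similarity
#
#   S = (1/N) * sum_j [ sum_i M[P_j, K_ij] ] * W_j
#
# with M a symmetric 24x24 matrix (BLOSUM62 before training) and W an
# 18-vector of position weights (all 1 before training). Scoring is
# vectorized through the 18x24 residue-count matrix C of the reference set:
# sum_i M[P_j, K_ij] = (C %*% M)[j, P_j].

#' Construct a LIR similarity-scoring model
#'
#' @param reference Tibble of reference positive windows with columns
#'   `accession`, `core_start`, `window_seq` (18 characters each).
#' @param matrix Symmetric 24 x 24 substitution matrix over [lir_alphabet()];
#'   defaults to BLOSUM62.
#' @param weights Numeric vector of 18 non-negative position weights;
#'   defaults to all 1.
#' @param seed Optional integer recording the training seed.
#' @param origin `"BLOSUM62"` for an untrained model, `"optimized"` after
#'   training.
#' @return An object of class `lir_model`.
#' @export
lir_model <- function(reference, matrix = blosum62(),
                      weights = rep(1, WINDOW_LEN),
                      seed = NULL, origin = "BLOSUM62") {
  stopifnot(all(c("accession", "core_start", "window_seq") %in% names(reference)))
  if (nrow(reference) == 0L) stop("reference positive set must be non-empty")
  stopifnot(identical(dim(matrix), c(24L, 24L)),
            isTRUE(all.equal(matrix, t(matrix))),
            length(weights) == WINDOW_LEN, all(weights >= 0))
  ref_enc <- aa_encode(reference$window_seq, width = WINDOW_LEN)
  m <- structure(
    list(matrix = matrix,
         weights = as.numeric(weights),
         reference = tibble::as_tibble(reference)[, c("accession", "core_start",
                                                      "window_seq")],
         ref_enc = ref_enc,
         ref_counts = ref_count_matrix(ref_enc),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         origin = origin),
    class = "lir_model"
  )
  m
}

# 18 x 24 matrix of residue counts per window position over the reference set
ref_count_matrix <- function(ref_enc) {
  counts <- matrix(0, nrow = WINDOW_LEN, ncol = 24L)
  for (j in seq_len(WINDOW_LEN)) {
    tab <- tabulate(ref_enc[, j], nbins = 24L)
    counts[j, ] <- tab
  }
  counts
}

#' @export
print.lir_model <- function(x, ...) {
  cat("<lir_model> ", x$origin, " matrix, N = ", nrow(x$reference),
      " reference windows\n", sep = "")
  cat("  weights:", paste(signif(x$weights, 3), collapse = " "), "\n")
  invisible(x)
}

# raw per-window totals sum_j W_j * (C M)[j, Q_qj]; divide by N (or N-1 with
# self-exclusion) to get the score
score_engine <- function(model, enc, exclude = rep(FALSE, nrow(enc))) {
  n_ref <- nrow(model$ref_enc)
  TW <- (model$ref_counts %*% model$matrix) * model$weights  # 18 x 24
  nq <- nrow(enc)
  lin <- (enc - 1L) * WINDOW_LEN + rep(seq_len(WINDOW_LEN), each = nq)
  tot <- rowSums(matrix(TW[lin], nrow = nq))
  if (any(exclude)) {
    if (n_ref < 2L) stop("self-exclusion leaves an empty reference set")
    idx <- which(exclude)
    self_lin <- (enc[idx, , drop = FALSE] - 1L) * 24L +
      enc[idx, , drop = FALSE]  # diagonal entries M[a, a]
    selfsim <- matrix(model$matrix[self_lin], nrow = length(idx)) %*%
      model$weights
    tot[idx] <- (tot[idx] - selfsim) / (n_ref - 1L)
    tot[-idx] <- tot[-idx] / n_ref
    if (length(idx) == nq) tot <- tot  # all excluded handled above
  } else {
    tot <- tot / n_ref
  }
  as.numeric(tot)
}

#' Score motif windows against the model's reference set
#'
#' Adds a `score` column: the average position-weighted substitution
#' similarity of each window against all reference positives. With
#' `exclude_self = TRUE`, windows whose (accession, core_start) identity
#' matches a reference entry are scored against the remaining N - 1
#' references (leave-one-out convention).
#'
#' @param windows Tibble with column `window_seq` (18-character strings);
#'   `accession` and `core_start` are required when `exclude_self = TRUE`.
#' @param model A [lir_model()].
#' @param exclude_self Apply the leave-one-out reference exclusion.
#' @return `windows` with a `score` column appended.
#' @export
score_windows <- function(windows, model, exclude_self = FALSE) {
  stopifnot(inherits(model, "lir_model"), "window_seq" %in% names(windows))
  if (nrow(windows) == 0L) {
    return(dplyr::mutate(windows, score = numeric(0)))
  }
  enc <- aa_encode(windows$window_seq, width = WINDOW_LEN)
  excl <- rep(FALSE, nrow(windows))
  if (exclude_self) {
    stopifnot(all(c("accession", "core_start") %in% names(windows)))
    key_ref <- paste(model$reference$accession, model$reference$core_start)
    excl <- paste(windows$accession, windows$core_start) %in% key_ref
  }
  dplyr::mutate(windows, score = score_engine(model, enc, excl))
}

#' Score a single window
#'
#' Scalar convenience wrapper around [score_windows()].
#'
#' @param window_seq One 18-character window string.
#' @param model A [lir_model()].
#' @param exclude_self Remove the identity-matched reference entry before
#'   averaging (requires `accession` and `core_start`).
#' @param accession,core_start Window identity used for self-exclusion.
#' @return The numeric score.
#' @export
similarity_score <- function(window_seq, model, exclude_self = FALSE,
                             accession = NULL, core_start = NULL) {
  w <- tibble::tibble(window_seq = window_seq,
                      accession = accession %||% NA_character_,
                      core_start = core_start %||% NA_integer_)
  score_windows(w, model, exclude_self = exclude_self)$score
}

`%||%` <- function(a, b) if (is.null(a)) b else a
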