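# Hill-climb training of the scoring model against the leave-one-out AUC.
#
# Two phases are alternated until neither improves:
#   PWD - position weight determination: the 18 window-position weights;
#   SMO - scoring matrix optimization: the 300 unique symmetric entries of
#         the 24x24 substitution matrix.
# Within a phase each step either perturbs one randomly chosen parameter by
# +1/-1 (random mutation) or sets one parameter to exactly 0 (random
# zeroing, the structural L1 device that prunes uninformative parameters).
# A proposal is adopted only if the objective strictly increases; a phase
# ends after `stop_patience` consecutive rejections.

# the 300 unordered (a, b) index pairs, a <= b
matrix_pairs <- function() {
  idx <- which(upper.tri(diag(24L), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

train_objective <- function(model, benchmark, lambda) {
  auc <- loo_auc(model, benchmark)
  if (lambda > 0) {
    pairs <- matrix_pairs()
    l1 <- sum(abs(model$weights)) + sum(abs(model$matrix[pairs]))
    list(auc = auc, objective = auc - lambda * l1)
  } else {
    list(auc = auc, objective = auc)
  }
}

#' Train the scoring model by stochastic hill climbing
#'
#' Starting from BLOSUM62 and unit weights, alternates a weight phase (PWD)
#' and a matrix phase (SMO). Each step proposes either a +1/-1 mutation of
#' one parameter or a zeroing of one parameter, and keeps it only when the
#' leave-one-out AUC on `benchmark` (minus an optional L1 penalty) strictly
#' increases, so the AUC trajectory is non-decreasing. Weights are
#' constrained to be non-negative; matrix entries are unconstrained. The
#' phase pair repeats until a full pass accepts nothing.
#'
#' @param benchmark Benchmark tibble from [build_benchmark()] (or the
#'   synthetic generator).
#' @param config A [lir_config()]; `seed` drives the proposal stream and
#'   `stop_patience` sets the consecutive-rejection cutoff per phase.
#' @param lambda Optional explicit L1 penalty coefficient subtracted from the
#'   AUC objective (default 0; the zeroing proposals already act as a
#'   structural sparsity device).
#' @param p_zero Probability that a step proposes a zeroing rather than a
#'   +1/-1 mutation.
#' @param verbose Emit one message per accepted proposal.
#' @return A list with `model` (the trained [lir_model()]), `initial_auc`,
#'   `final_auc`, and `trace` (tibble of accepted steps: `step`, `phase`,
#'   `kind`, `param`, `old`, `new`, `auc`).
#' @export
train_lir_model <- function(benchmark, config = lir_config(), lambda = 0,
                            p_zero = 0.1, verbose = FALSE) {
  ref <- dplyr::filter(benchmark, .data$label == "positive")
  if (nrow(ref) < 2L || !any(benchmark$label == "negative")) {
    stop("benchmark needs >= 2 positives and >= 1 negative to train")
  }
  model <- lir_model(ref, seed = config$seed)
  obj <- train_objective(model, benchmark, lambda)
  auc0 <- obj$auc
  pairs <- matrix_pairs()
  trace <- list()
  step <- 0L

  withr::with_seed(config$seed, {
    repeat {
      accepted_in_pass <- FALSE
      for (phase in c("PWD", "SMO")) {
        rejected_streak <- 0L
        while (rejected_streak < config$stop_patience) {
          step <- step + 1L
          zero <- stats::runif(1) < p_zero
          if (phase == "PWD") {
            j <- sample.int(WINDOW_LEN, 1L)
            old <- model$weights[j]
            new <- if (zero) 0 else old + sample(c(-1, 1), 1L)
            param <- paste0("W", j)
            valid <- new >= 0 && new != old
          } else {
            p <- sample.int(nrow(pairs), 1L)
            a <- pairs[p, 1L]; b <- pairs[p, 2L]
            old <- model$matrix[a, b]
            new <- if (zero) 0 else old + sample(c(-1, 1), 1L)
            param <- paste0("S_", lir_alphabet()[a], lir_alphabet()[b])
            valid <- new != old
          }
          if (!valid) {
            rejected_streak <- rejected_streak + 1L
            next
          }
          cand <- model
          if (phase == "PWD") {
            cand$weights[j] <- new
          } else {
            cand$matrix[a, b] <- new
            cand$matrix[b, a] <- new
          }
          cand_obj <- train_objective(cand, benchmark, lambda)
          if (cand_obj$objective > obj$objective) {
            model <- cand
            obj <- cand_obj
            rejected_streak <- 0L
            accepted_in_pass <- TRUE
            trace[[length(trace) + 1L]] <- tibble::tibble(
              step = step, phase = phase,
              kind = if (zero) "zero" else "mutate",
              param = param, old = old, new = new, auc = obj$auc)
            if (verbose) {
              message(sprintf("accept step=%d phase=%s %s %s %g -> %g AUC=%.6f",
                              step, phase, if (zero) "zero" else "mutate",
                              param, old, new, obj$auc))
            }
          } else {
            rejected_streak <- rejected_streak + 1L
          }
        }
      }
      if (!accepted_in_pass) break
    }
  })

  model$origin <- "optimized"
  structure(
    list(model = model,
         initial_auc = auc0,
         final_auc = obj$auc,
         trace = if (length(trace)) dplyr::bind_rows(trace) else
           tibble::tibble(step = integer(), phase = character(),
                          kind = character(), param = character(),
                          old = numeric(), new = numeric(), auc = numeric())),
    class = "lir_training"
  )
}

#' @export
print.lir_training <- function(x, ...) {
  cat("<lir_training> LOO AUC", signif(x$initial_auc, 6), "->",
      signif(x$final_auc, 6), "over", nrow(x$trace), "accepted proposals\n")
  invisible(x)
}
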