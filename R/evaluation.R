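# Threshold metrics, rank-based ROC/AUC, and cross-validation schemes.

#' Classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value, and the Matthews correlation coefficient. A metric whose
#' denominator is zero is reported as `NA` rather than raising an error.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return A one-row tibble with columns `ac`, `sn`, `sp`, `ppv`, `npv`, `mcc`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(prod(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  tibble::tibble(
    ac  = div(tp + tn, tp + fp + tn + fn),
    sn  = div(tp, tp + fn),
    sp  = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    mcc = if (mcc_den > 0) (tp * tn - fn * fp) / mcc_den else NA_real_
  )
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation: the probability that a randomly
#' chosen positive outscores a randomly chosen negative, ties counted 1/2.
#'
#' @param score Numeric scores.
#' @param label Labels, `"positive"` / `"negative"` (or a logical vector with
#'   `TRUE` = positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(score, label) {
  pos <- if (is.logical(label)) label else label == "positive"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs at least one positive and one negative")
  }
  r <- rank(score)  # average ranks implement the ties-1/2 convention
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sensitivity and 1 - specificity at every distinct score threshold.
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `sn`, `one_minus_sp`.
#' @export
roc_points <- function(score, label) {
  pos <- if (is.logical(label)) label else label == "positive"
  thr <- sort(unique(score), decreasing = TRUE)
  purrr::map_dfr(thr, function(t) {
    pred <- score >= t
    tibble::tibble(threshold = t,
                   sn = sum(pred & pos) / sum(pos),
                   one_minus_sp = sum(pred & !pos) / sum(!pos))
  })
}

#' Leave-one-out AUC of a model on a benchmark
#'
#' Scores every benchmark window, removing each positive from the reference
#' set when scoring itself, and returns the AUC over all windows. With the
#' untrained model (BLOSUM62 matrix, unit weights) this is the baseline AUC
#' that training starts from.
#'
#' @param model A [lir_model()] whose reference set is the benchmark's
#'   positives.
#' @param benchmark Tibble with columns `accession`, `core_start`,
#'   `window_seq`, `label`.
#' @return The LOO AUC.
#' @export
loo_auc <- function(model, benchmark) {
  scored <- score_windows(benchmark, model, exclude_self = TRUE)
  roc_auc(scored$score, scored$label)
}

#' Baseline leave-one-out AUC of a benchmark
#'
#' Builds the untrained model (BLOSUM62, unit weights, reference = the
#' benchmark's positives) and computes its LOO AUC.
#'
#' @param benchmark Benchmark tibble as produced by [build_benchmark()].
#' @return The untrained LOO AUC.
#' @export
initial_auc <- function(benchmark) {
  ref <- dplyr::filter(benchmark, .data$label == "positive")
  if (nrow(ref) < 2L || !any(benchmark$label == "negative")) {
    stop("benchmark needs >= 2 positives and >= 1 negative")
  }
  loo_auc(lir_model(ref), benchmark)
}

#' Cross-validate a scoring model on a benchmark
#'
#' `scheme = "loo"` scores every window once, excluding each positive from
#' the reference set when it is itself scored. `scheme = "kfold"` splits the
#' benchmark into `k` label-stratified folds; each fold is scored by a model
#' whose reference set (and, when a `trainer` is supplied, whose trained
#' parameters) comes from the other folds only.
#'
#' @param benchmark Benchmark tibble (`accession`, `core_start`, `window_seq`,
#'   `label`).
#' @param scheme `"loo"` or `"kfold"`.
#' @param k Number of folds for `"kfold"` (the conventional choices are 4, 6,
#'   8, 10).
#' @param seed Integer seed for the stratified fold shuffle.
#' @param trainer Optional function `benchmark -> lir_model` fitted on the
#'   training portion; defaults to the untrained model over the training
#'   positives.
#' @return A list with `scores` (tibble of held-out window scores and fold
#'   ids), `fold_auc` (tibble), and `auc` (pooled AUC over all held-out
#'   scores).
#' @export
cross_validate <- function(benchmark, scheme = c("loo", "kfold"), k = 10L,
                           seed = 1L, trainer = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("accession", "core_start", "window_seq", "label")
                %in% names(benchmark)))
  baseline_trainer <- function(bm) {
    lir_model(dplyr::filter(bm, .data$label == "positive"))
  }
  trainer <- trainer %||% baseline_trainer

  if (scheme == "loo") {
    model <- trainer(benchmark)
    scored <- score_windows(benchmark, model, exclude_self = TRUE)
    scored$fold <- seq_len(nrow(scored))
    fold_auc <- tibble::tibble(fold = NA_integer_,
                               auc = roc_auc(scored$score, scored$label))
    return(list(scores = scored, fold_auc = fold_auc, auc = fold_auc$auc[1]))
  }

  stopifnot(k >= 2L)
  fold <- integer(nrow(benchmark))
  withr::with_seed(seed, {
    for (lab in unique(benchmark$label)) {
      idx <- which(benchmark$label == lab)
      if (length(idx) < k) stop("label '", lab, "' has fewer members than folds")
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  scored <- purrr::map_dfr(seq_len(k), function(f) {
    train_bm <- benchmark[fold != f, , drop = FALSE]
    test_bm <- benchmark[fold == f, , drop = FALSE]
    if (length(unique(train_bm$label)) < 2L ||
        length(unique(test_bm$label)) < 2L) {
      stop("fold ", f, " leaves a single-class split")
    }
    model <- trainer(train_bm)
    dplyr::mutate(score_windows(test_bm, model, exclude_self = FALSE),
                  fold = f)
  })
  fold_auc <- scored |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(auc = roc_auc(.data$score, .data$label), .groups = "drop")
  list(scores = scored, fold_auc = fold_auc,
       auc = roc_auc(scored$score, scored$label))
}

#' Point metrics at the MCC-optimal threshold
#'
#' Scans all observed scores as thresholds and reports the six threshold
#' metrics at the cutoff maximizing MCC, together with that cutoff.
#'
#' @inheritParams roc_auc
#' @return One-row tibble: `threshold`, `ac`, `sn`, `sp`, `ppv`, `npv`, `mcc`.
#' @export
best_point_metrics <- function(score, label) {
  pos <- if (is.logical(label)) label else label == "positive"
  thr <- sort(unique(score))
  rows <- purrr::map_dfr(thr, function(t) {
    pred <- score >= t
    m <- classification_metrics(sum(pred & pos), sum(!pred & !pos),
                                sum(pred & !pos), sum(!pred & pos))
    dplyr::mutate(m, threshold = t)
  })
  rows[which.max(rows$mcc), c("threshold", "ac", "sn", "sp", "ppv", "npv", "mcc")]
}
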