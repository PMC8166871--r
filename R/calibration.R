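# Calibration of raw similarity scores to Bayesian posterior probabilities
#
#   p(P | S) = f(S|P) p(P) / ( f(S|P) p(P) + f(S|N) p(N) )
#
# with class-conditional densities f(S|P), f(S|N) fitted as one-dimensional
# Gaussian kernel densities over min-max-scaled scores (bandwidths by the
# one-dimensional maximum-likelihood grid search), prior p(P) set to the
# model's leave-one-out AUC, and p(N) = 1.

kde1d_eval <- function(points, h, s) {
  D <- outer(s, points, "-")^2
  rowSums(exp(-D / (2 * h^2))) / (length(points) * h * sqrt(2 * pi))
}

#' Construct a score calibration directly
#'
#' Low-level constructor; [calibrate_model()] builds one from a model and a
#' benchmark.
#'
#' @param pos_points,neg_points Min-max-scaled scores of the positive and
#'   negative windows (in \[0, 1\]).
#' @param h_pos,h_neg Kernel bandwidths of the two class densities.
#' @param prior_pos Prior belief in the positive class, conventionally the
#'   model's AUC; must lie in (0, 1].
#' @param scale_min,scale_max Raw-score bounds used for min-max scaling.
#' @return An object of class `lir_calibration`.
#' @export
lir_calibration <- function(pos_points, neg_points, h_pos, h_neg,
                            prior_pos, scale_min, scale_max) {
  stopifnot(length(pos_points) >= 1, length(neg_points) >= 1,
            h_pos > 0, h_neg > 0, prior_pos > 0, prior_pos <= 1,
            scale_max > scale_min)
  structure(list(pos_points = pos_points, neg_points = neg_points,
                 h_pos = h_pos, h_neg = h_neg,
                 prior_pos = prior_pos, prior_neg = 1,
                 scale_min = scale_min, scale_max = scale_max),
            class = "lir_calibration")
}

#' @export
print.lir_calibration <- function(x, ...) {
  cat("<lir_calibration> p(P) =", signif(x$prior_pos, 4),
      "| h_pos =", x$h_pos, "h_neg =", x$h_neg,
      "| raw range [", signif(x$scale_min, 4), ",",
      signif(x$scale_max, 4), "]\n")
  invisible(x)
}

#' Calibrate a model's scores to posterior probabilities
#'
#' Scores the benchmark (positives leave-one-out against the reference set),
#' min-max-scales the scores, fits Gaussian kernel densities to the positive
#' and negative score distributions with maximum-likelihood bandwidths, and
#' sets the positive prior to the leave-one-out AUC (negative prior 1).
#'
#' @param model A [lir_model()].
#' @param benchmark Benchmark tibble with `label` column.
#' @param config A [lir_config()].
#' @return A `lir_calibration` object.
#' @export
calibrate_model <- function(model, benchmark, config = lir_config()) {
  scored <- score_windows(benchmark, model, exclude_self = TRUE)
  lo <- min(scored$score)
  hi <- max(scored$score)
  if (hi <= lo) stop("degenerate score range; cannot calibrate")
  s <- (scored$score - lo) / (hi - lo)
  pos <- s[scored$label == "positive"]
  neg <- s[scored$label == "negative"]
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("calibration needs >= 2 windows of each label")
  }
  lir_calibration(
    pos_points = pos, neg_points = neg,
    h_pos = select_bandwidth_1d(pos, config),
    h_neg = select_bandwidth_1d(neg, config),
    prior_pos = roc_auc(scored$score, scored$label),
    scale_min = lo, scale_max = hi
  )
}

#' Transform raw scores to Bayesian posterior probabilities
#'
#' Raw scores are min-max scaled with the calibration's bounds (clipped to
#' \[0, 1\] outside them) and mapped through
#' `f(S|P) p(P) / (f(S|P) p(P) + f(S|N) p(N))`.
#'
#' @param raw_score Numeric vector of raw similarity scores.
#' @param calibration A [lir_calibration()].
#' @return Posterior probabilities in \[0, 1\].
#' @export
bpp_transform <- function(raw_score, calibration) {
  stopifnot(inherits(calibration, "lir_calibration"))
  s <- (raw_score - calibration$scale_min) /
    (calibration$scale_max - calibration$scale_min)
  s <- pmin(1, pmax(0, s))
  fp <- kde1d_eval(calibration$pos_points, calibration$h_pos, s)
  fn <- kde1d_eval(calibration$neg_points, calibration$h_neg, s)
  num <- fp * calibration$prior_pos
  den <- num + fn * calibration$prior_neg
  if (any(den <= 0)) {
    stop("both class densities vanish at a query score; calibration degenerate")
  }
  num / den
}
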