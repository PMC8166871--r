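#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve from scored, labelled windows
#'
#' @param score Numeric scores.
#' @param label `"positive"` / `"negative"` labels (or logical).
#' @return A ggplot object.
#' @export
plot_roc <- function(score, label) {
  pts <- roc_points(score, label)
  auc <- roc_auc(score, label)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$one_minus_sp, y = .data$sn)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.4f)", auc)) +
    ggplot2::theme_minimal()
}

#' Position-weight profile of a scoring model
#'
#' @param object A [lir_model()].
#' @param ... Unused.
#' @return A ggplot object: trained weight per window offset, anchors marked.
#' @export
autoplot.lir_model <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$offset, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = c(0, 3), linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = td$offset) +
    ggplot2::labs(x = "window offset (0 = aromatic anchor)",
                  y = "position weight") +
    ggplot2::theme_minimal()
}

#' AUC trajectory of a training run
#'
#' @param object The list returned by [train_lir_model()].
#' @param ... Unused.
#' @return A ggplot object: LOO AUC after each accepted proposal.
#' @export
autoplot.lir_training <- function(object, ...) {
  tr <- object$trace
  start <- tibble::tibble(step = 0L, auc = object$initial_auc,
                          phase = "start")
  dat <- dplyr::bind_rows(start, tr[, c("step", "auc", "phase")])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$step, y = .data$auc)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase), size = 1) +
    ggplot2::labs(x = "proposal step", y = "leave-one-out AUC") +
    ggplot2::theme_minimal()
}

#' Contour view of the (x, y) pair density
#'
#' @param object A [lam_density()].
#' @param grid_n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object: filled density contours with the score pairs
#'   overplotted.
#' @export
autoplot.lam_density <- function(object, grid_n = 101L, ...) {
  g <- seq(0, 1, length.out = grid_n)
  grid <- tidyr::expand_grid(x = g, y = g)
  grid$f <- eval_pair_density(object, grid$x, grid$y)
  pts <- tibble::as_tibble(object$points)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_contour_filled(ggplot2::aes(z = .data$f), alpha = 0.8) +
    ggplot2::geom_point(data = pts, size = 0.4, alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "original posterior x", y = "mutant posterior y",
                  fill = "density") +
    ggplot2::theme_minimal()
}

#' Scatter of LAM calls in the (x, y) plane
#'
#' @param calls Tibble from [call_lams()].
#' @return A ggplot object: original vs mutant posterior, coloured by
#'   verdict, with the score-threshold guides.
#' @export
plot_lam_calls <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$verdict)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(TypeI = "#d95f02",
                                            TypeII = "#7570b3",
                                            none = "grey60")) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "original posterior x", y = "mutant posterior y") +
    ggplot2::theme_minimal()
}
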