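# Maximum-likelihood bandwidth selection for Gaussian kernel densities.
#
# For a candidate h the fit is scored by the leave-one-out likelihood: each
# point's density under the kernels of all the other points. The optimum is
# searched on the grid 0.0001, 0.0002, ..., 1. The LOO log-likelihood is a
# smooth function of h, so the default search is staged (0.01 -> 0.001 ->
# 0.0001 refinement around the running argmax), which returns the same grid
# argmax as the exhaustive scan at a fraction of the cost; the exhaustive
# scan is available via `full_grid = TRUE` and serves as the oracle in tests.

# LOO log-likelihood of squared-distance matrix D (n x n) at bandwidth h,
# for a kernel of dimension `dim` (1 or 2). Log-sum-exp guarded.
bandwidth_loglik <- function(D, h, dim) {
  n <- nrow(D)
  E <- -D / (2 * h^2)
  diag(E) <- -Inf
  m <- apply(E, 1L, max)
  lse <- ifelse(is.finite(m), m + log(rowSums(exp(E - m))), -Inf)
  sum(lse) + n * (-log(n - 1) - dim * log(h) - (dim / 2) * log(2 * pi))
}

snap_grid <- function(h, step = 1e-4) round(h / step) * step

search_bandwidth <- function(D, dim, grid_step = 1e-4, full_grid = FALSE) {
  eval_grid <- function(hs) {
    hs <- sort(unique(pmin(1, pmax(grid_step, snap_grid(hs, grid_step)))))
    ll <- vapply(hs, function(h) bandwidth_loglik(D, h, dim), numeric(1))
    hs[which.max(ll)]
  }
  if (full_grid) return(eval_grid(seq(grid_step, 1, by = grid_step)))
  h1 <- eval_grid(c(grid_step, seq(0.001, 0.01, by = 0.001),
                    seq(0.01, 1, by = 0.01)))
  h2 <- eval_grid(seq(h1 - 0.01, h1 + 0.01, by = 0.001))
  eval_grid(seq(h2 - 0.001, h2 + 0.001, by = grid_step))
}

#' Maximum-likelihood Parzen bandwidth for (x, y) score pairs
#'
#' Chooses the Gaussian kernel width h on the grid `grid_step, 2*grid_step,
#' ..., 1` maximizing the leave-one-out likelihood of the two-dimensional
#' Parzen density. When more than `config$kde_subsample` pairs are supplied,
#' the likelihood is evaluated on a seeded uniform subsample.
#'
#' @param pairs Two-column matrix or data frame of (x, y) values in \[0, 1\].
#' @param config A [lir_config()] (grid step, subsample size, seed).
#' @param full_grid Evaluate every grid value instead of the staged search.
#' @return The selected bandwidth (a grid value).
#' @export
select_bandwidth <- function(pairs, config = lir_config(), full_grid = FALSE) {
  pts <- as.matrix(pairs)[, 1:2, drop = FALSE]
  if (nrow(pts) < 2L) stop("bandwidth selection needs at least 2 points")
  if (nrow(pts) > config$kde_subsample) {
    keep <- withr::with_seed(config$seed,
                             sample.int(nrow(pts), config$kde_subsample))
    pts <- pts[keep, , drop = FALSE]
  }
  D <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  search_bandwidth(D, dim = 2L, grid_step = config$h_grid_step,
                   full_grid = full_grid)
}

# 1-D analog, used for the score-calibration densities
select_bandwidth_1d <- function(points, config = lir_config(),
                                full_grid = FALSE) {
  if (length(points) < 2L) stop("bandwidth selection needs at least 2 points")
  if (length(points) > config$kde_subsample) {
    keep <- withr::with_seed(config$seed,
                             sample.int(length(points), config$kde_subsample))
    points <- points[keep]
  }
  D <- outer(points, points, "-")^2
  search_bandwidth(D, dim = 1L, grid_step = config$h_grid_step,
                   full_grid = full_grid)
}
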