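# The two-dimensional Parzen-window density over (x, y) posterior pairs
# (original score x, mutant score y) and the conditional tail p-values that
# decide whether a mutation's y is surprising given its x.
#
#   f(x, y) = 1/(n h^2) * sum_i 1/(2 pi) exp(-((x-x_i)^2 + (y-y_i)^2)/(2 h^2))

#' Construct a Parzen pair density with a given bandwidth
#'
#' Low-level constructor; see [fit_pair_density()] for the usual entry point
#' that also selects the bandwidth.
#'
#' @param pairs Two-column matrix or data frame of (x, y) values in \[0, 1\].
#' @param h Gaussian kernel bandwidth (> 0).
#' @return An object of class `lam_density`.
#' @export
lam_density <- function(pairs, h) {
  pts <- as.matrix(pairs)[, 1:2, drop = FALSE]
  stopifnot(nrow(pts) >= 1L, h > 0,
            all(pts >= 0 & pts <= 1))
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, h = h, n = nrow(pts)), class = "lam_density")
}

#' @export
print.lam_density <- function(x, ...) {
  cat("<lam_density> n =", x$n, "pairs, h =", x$h, "\n")
  invisible(x)
}

#' Fit the Parzen pair density with maximum-likelihood bandwidth
#'
#' @inheritParams lam_density
#' @param config A [lir_config()] passed to [select_bandwidth()].
#' @param full_grid Evaluate the full bandwidth grid (oracle mode).
#' @return A `lam_density` object.
#' @export
fit_pair_density <- function(pairs, config = lir_config(), full_grid = FALSE) {
  pts <- as.matrix(pairs)[, 1:2, drop = FALSE]
  if (nrow(pts) < 2L) stop("pair density needs at least 2 points")
  lam_density(pts, select_bandwidth(pts, config, full_grid = full_grid))
}

#' Evaluate the Parzen pair density
#'
#' @param density A [lam_density()].
#' @param x,y Numeric vectors of equal length: query coordinates.
#' @return Density values `f(x, y)`.
#' @export
eval_pair_density <- function(density, x, y) {
  stopifnot(inherits(density, "lam_density"), length(x) == length(y))
  h <- density$h
  xi <- density$points[, 1]
  yi <- density$points[, 2]
  D <- outer(x, xi, "-")^2 + outer(y, yi, "-")^2
  rowSums(exp(-D / (2 * h^2))) / (density$n * h^2 * 2 * pi)
}

# Conditional tail p-values for many (x, y, direction) triples at once.
# f(y | x) is f(x, y) renormalized over y in [0, 1] on a step-0.001 grid;
# "gain" tests P(Y >= y | x), "loss" tests P(Y <= y | x). The kernel is
# separable, so f(x_r, t_g) = sum_i a_ri * b_gi = (A B^T)_rg up to a
# constant that cancels in the conditional.
conditional_pvalues <- function(density, x, y, direction,
                                y_step = 0.001, chunk = 512L) {
  stopifnot(inherits(density, "lam_density"),
            length(x) == length(y), length(direction) == length(x),
            all(direction %in% c("gain", "loss")),
            all(x >= 0 & x <= 1), all(y >= 0 & y <= 1))
  h <- density$h
  xi <- density$points[, 1]
  yi <- density$points[, 2]
  tg <- seq(0, 1, by = y_step)
  B <- exp(-outer(tg, yi, "-")^2 / (2 * h^2))  # G x n
  out <- numeric(length(x))
  for (lo in seq(1, length(x), by = chunk)) {
    idx <- lo:min(lo + chunk - 1L, length(x))
    lA <- -outer(x[idx], xi, "-")^2 / (2 * h^2)
    m <- apply(lA, 1L, max)  # rescale per row to dodge underflow at small h
    # a query x whose nearest kernel underflows outright has no support
    m[m < log(.Machine$double.xmin)] <- NA_real_
    Fm <- exp(lA - m) %*% t(B)  # rows prop. to f(x_r, t_g)
    dt <- y_step
    cum <- cbind(0, t(apply((Fm[, -1, drop = FALSE] +
                             Fm[, -ncol(Fm), drop = FALSE]) / 2 * dt,
                            1L, cumsum)))
    tot <- cum[, ncol(cum)]
    Fy <- vapply(seq_along(idx), function(r) {
      if (tot[r] <= 0 || !is.finite(tot[r])) return(NA_real_)
      stats::approx(tg, cum[r, ], xout = y[idx[r]], rule = 2)$y / tot[r]
    }, numeric(1))
    out[idx] <- ifelse(direction[idx] == "gain", 1 - Fy, Fy)
  }
  bad <- is.na(out)
  if (any(bad)) {
    warning(sum(bad), " quer(ies) with x outside the density support; ",
            "p-value set to NA")
  }
  pmin(1, pmax(0, out))
}

#' Conditional tail p-value of a mutant score given the original score
#'
#' Estimates the conditional density of Y given `x` from the fitted pair
#' density (renormalized over \[0, 1\] on a 0.001 grid, trapezoidal
#' integration) and returns the upper tail `P(Y >= y | x)` for
#' `direction = "gain"` or the lower tail `P(Y <= y | x)` for
#' `direction = "loss"`.
#'
#' @param density A [lam_density()].
#' @param x,y Scalars in \[0, 1\].
#' @param direction `"gain"` or `"loss"`.
#' @return The tail probability.
#' @export
conditional_pvalue <- function(density, x, y, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  p <- suppressWarnings(conditional_pvalues(density, x, y, direction))
  if (is.na(p)) stop("x = ", x, " lies outside the support of the density")
  p
}
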