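test_that("the Parzen density evaluates to its closed form", {
  # single kernel at its own center: 1 / (2 pi h^2)
  d1 <- lam_density(cbind(0.5, 0.5), h = 0.1)
  expect_equal(eval_pair_density(d1, 0.5, 0.5), 1 / (2 * pi * 0.01))

  # two-kernel mixture reproduced pointwise
  pts <- rbind(c(0.3, 0.4), c(0.7, 0.6))
  d2 <- lam_density(pts, h = 0.15)
  f_manual <- function(x, y) {
    mean(exp(-((x - pts[, 1])^2 + (y - pts[, 2])^2) / (2 * 0.15^2))) /
      (2 * pi * 0.15^2)
  }
  set.seed(77)
  for (i in 1:50) {
    x <- runif(1); y <- runif(1)
    expect_equal(eval_pair_density(d2, x, y), f_manual(x, y),
                 tolerance = 1e-12)
  }

  # exchangeability under swapping mirror-image points
  d_swap <- lam_density(pts[2:1, ], h = 0.15)
  expect_equal(eval_pair_density(d_swap, 0.41, 0.52),
               eval_pair_density(d2, 0.41, 0.52))
})

test_that("the Parzen density integrates to one", {
  set.seed(79)
  pts <- cbind(runif(20, 0.3, 0.7), runif(20, 0.3, 0.7))
  d <- lam_density(pts, h = 0.05)
  g <- seq(0.3 - 4 * 0.05, 0.7 + 4 * 0.05, length.out = 201)
  dx <- diff(g)[1]
  vals <- outer(g, g, function(x, y) eval_pair_density(d, x, y))
  expect_equal(sum(vals) * dx^2, 1, tolerance = 1e-3)
})

test_that("maximum-likelihood bandwidth recovers closed-form optima", {
  # coincident points: likelihood grows as h shrinks -> grid minimum
  expect_equal(select_bandwidth(rbind(c(0.5, 0.5), c(0.5, 0.5))), 1e-4)

  # two points at distance d: optimum h = d / sqrt(2), grid-snapped
  p <- rbind(c(0.4, 0.5), c(0.6, 0.5))  # d = 0.2
  expect_equal(select_bandwidth(p), 0.1414)

  # second geometry: grid argmax of the closed-form two-point log-likelihood
  # g(h) = -2 log h - d^2 / (2 h^2) serves as the oracle
  p2 <- rbind(c(0.3, 0.3), c(0.45, 0.55))
  d2 <- sqrt(sum((p2[1, ] - p2[2, ])^2))
  grid <- seq(1e-4, 1, by = 1e-4)
  oracle <- grid[which.max(-2 * log(grid) - d2^2 / (2 * grid^2))]
  expect_equal(select_bandwidth(p2), oracle)
  expect_equal(oracle, round(d2 / sqrt(2), 4))  # here they coincide
})

test_that("the staged grid search matches the exhaustive scan", {
  set.seed(83)
  for (i in 1:3) {
    pts <- cbind(runif(40), runif(40))
    cfg <- lir_config(seed = i)
    expect_equal(select_bandwidth(pts, cfg),
                 select_bandwidth(pts, cfg, full_grid = TRUE))
  }
})

test_that("selected bandwidth is within a factor two of the Silverman rule", {
  set.seed(89)
  ok <- vapply(1:3, function(k) {
    pts <- cbind(rnorm(500, 0.5, 0.1), rnorm(500, 0.5, 0.1))
    pts <- pmin(pmax(pts, 0), 1)
    h <- select_bandwidth(pts, lir_config(seed = k))
    # 2-D Gaussian reference rule: h = sigma * n^(-1/6)
    sigma <- sqrt(mean(c(var(pts[, 1]), var(pts[, 2]))))
    h_ref <- sigma * nrow(pts)^(-1 / 6)
    h > h_ref / 2 && h < h_ref * 2
  }, logical(1))
  expect_true(all(ok))
})

test_that("bandwidth subsampling is seeded and stays near the full argmax", {
  set.seed(97)
  pts <- cbind(runif(600), runif(600))
  cfg_small <- lir_config(seed = 5L, kde_subsample = 200L)
  h1 <- select_bandwidth(pts, cfg_small)
  h2 <- select_bandwidth(pts, cfg_small)
  expect_identical(h1, h2)
  h_full <- select_bandwidth(pts, lir_config(seed = 5L))
  expect_lt(abs(log(h1 / h_full)), log(2.5))
})

test_that("conditional tail probabilities behave like proper tails", {
  # single kernel at (0.5, 0.5): conditional symmetric about 0.5
  d <- lam_density(cbind(0.5, 0.5), h = 0.08)
  expect_equal(conditional_pvalue(d, 0.5, 0.5, "gain"), 0.5, tolerance = 1e-9)
  expect_equal(conditional_pvalue(d, 0.5, 0.5, "loss"), 0.5, tolerance = 1e-9)

  # gain tail non-increasing in y at fixed x
  set.seed(101)
  pts <- cbind(runif(50), runif(50))
  dd <- lam_density(pts, h = 0.1)
  ys <- seq(0, 1, by = 0.05)
  pg <- vapply(ys, function(y) conditional_pvalue(dd, 0.4, y, "gain"),
               numeric(1))
  expect_true(all(diff(pg) <= 1e-9))

  # complementary tails sum to one (shared grid cell)
  for (y in c(0.12, 0.5, 0.93)) {
    expect_equal(conditional_pvalue(dd, 0.4, y, "gain") +
                   conditional_pvalue(dd, 0.4, y, "loss"), 1,
                 tolerance = 1e-6)
  }
})

test_that("queries outside the density support are rejected", {
  d <- lam_density(cbind(0.1, 0.1), h = 1e-4)
  expect_error(conditional_pvalue(d, 0.99, 0.5, "gain"), "support")
})

test_that("density fitting validates its inputs", {
  expect_error(fit_pair_density(cbind(0.5, 0.5)), "at least 2")
  expect_error(lam_density(cbind(1.5, 0.5), h = 0.1))
  expect_error(lam_density(cbind(0.5, 0.5), h = 0))
})
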