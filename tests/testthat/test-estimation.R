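# The shared fitting engine: RMSD objective, multi-start minimisation,
# bootstrap resampling, Monte-Carlo propagation.

test_that("rmsd matches its closed form and enforces equal lengths", {
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsd(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmsd(1, 4), 3)
  expect_error(rmsd(1:3, 1:2), class = "caprokin_contract_error")
  expect_error(rmsd(numeric(), numeric()), class = "caprokin_contract_error")
})

test_that("minimize_rmsd recovers a noiseless quadratic and respects contracts", {
  x <- seq(-2, 2, length.out = 21)
  y <- 2 * x^2
  model <- function(p, xx) p[1] * xx^2
  est <- minimize_rmsd(model, x, y, lower = 0, upper = 10,
                       starts = matrix(c(0.5, 5, 9), ncol = 1),
                       par_names = "a")
  expect_true(est$converged)
  expect_equal(unname(est$values["a"]), 2, tolerance = 1e-6)
  expect_lt(est$rmsd, 1e-8)

  # fewer points than parameters
  expect_error(
    minimize_rmsd(model, 1, 2, lower = c(0, 0), upper = c(1, 1),
                  starts = matrix(c(0.5, 0.5), ncol = 2)),
    class = "caprokin_contract_error")
  # non-finite bounds
  expect_error(
    minimize_rmsd(model, x, y, lower = 0, upper = Inf,
                  starts = matrix(1)),
    class = "caprokin_contract_error")
})

test_that("minimize_rmsd is deterministic and never worse than its starts", {
  x <- seq(0, 120, length.out = 40)
  set.seed(42)
  for (i in 1:5) {
    A <- runif(1, 0.5, 2); mu <- runif(1, 0.02, 0.1); lam <- runif(1, 0, 20)
    y <- gompertz_curve(x, A, mu, lam) + rnorm(40, 0, 0.02)
    model <- function(p, tt) gompertz_curve(tt, p[1], p[2], p[3])
    starts <- as.matrix(expand.grid(A = c(0.5, 1, 2), mu = c(0.02, 0.05, 0.1),
                                    lam = c(1, 10, 20)))
    lower <- c(1e-8, 1e-8, 0); upper <- c(4, 1, 120)
    e1 <- minimize_rmsd(model, x, y, lower, upper, starts)
    e2 <- minimize_rmsd(model, x, y, lower, upper, starts)
    expect_identical(e1, e2)
    start_objs <- apply(starts, 1, function(p) rmsd(y, model(p, x)))
    expect_lte(e1$rmsd, min(start_objs) + 1e-12)
  }
})

test_that("bootstrap on noiseless data collapses to the point estimate", {
  x <- seq(0, 10, length.out = 12)
  y <- 3 * x
  model <- function(p, xx) p[1] * xx
  est <- minimize_rmsd(model, x, y, 0, 10, matrix(c(1, 5), ncol = 1), "a")
  bd <- bootstrap_parameters(model, x, y, est, 0, 10, scheme = "residual",
                             n_boot = 50, seed = 7)
  expect_equal(unname(bd$sd), 0, tolerance = 1e-10)
  expect_true(all(abs(bd$samples - 3) < 1e-8))
})

test_that("bootstrap is bit-identical for a fixed seed and leaves the RNG alone", {
  set.seed(123)
  x <- seq(0, 10, length.out = 20)
  y <- 2 * x + rnorm(20, 0, 0.3)
  model <- function(p, xx) p[1] * xx
  est <- minimize_rmsd(model, x, y, 0, 10, matrix(c(1, 5), ncol = 1), "a")
  set.seed(99)
  before <- .Random.seed
  b1 <- bootstrap_parameters(model, x, y, est, 0, 10, "residual",
                             n_boot = 100, seed = 11)
  expect_identical(.Random.seed, before)
  b2 <- bootstrap_parameters(model, x, y, est, 0, 10, "residual",
                             n_boot = 100, seed = 11)
  expect_identical(b1, b2)
})

test_that("doubling the noise roughly doubles the bootstrap sd", {
  x <- seq(0.1, 2, length.out = 20)
  model <- function(p, xx) p[1] * xx
  ratios <- vapply(1:50, function(r) {
    set.seed(1000 + r)
    eps <- rnorm(20)
    sds <- vapply(c(0.05, 0.10), function(s) {
      y <- 2 * x + s * eps
      est <- minimize_rmsd(model, x, y, 0, 10, matrix(c(1, 4), ncol = 1), "a")
      bd <- bootstrap_parameters(model, x, y, est, 0, 10, "residual",
                                 n_boot = 500, seed = r)
      unname(bd$sd)
    }, numeric(1))
    sds[2] / sds[1]
  }, numeric(1))
  expect_gt(mean(ratios), 1.6)
  expect_lt(mean(ratios), 2.4)
})

test_that("Monte-Carlo propagation matches identities and the delta method", {
  # identity on a degenerate distribution
  dd <- make_param_dist(matrix(5, nrow = 10, ncol = 1,
                               dimnames = list(NULL, "a")))
  mc <- propagate_uncertainty(dd, function(p) p[["a"]], n_mc = 1000, seed = 3)
  expect_equal(mc$mean, 5)
  expect_equal(mc$sd, 0)

  # scaling a parameter scales the sd exactly (same draws, same seed)
  set.seed(8)
  dist <- make_param_dist(matrix(rnorm(400, 1, 0.1), ncol = 1,
                                 dimnames = list(NULL, "th")))
  m1 <- propagate_uncertainty(dist, function(p) p[["th"]], 5000, seed = 4)
  m2 <- propagate_uncertainty(dist, function(p) 2 * p[["th"]], 5000, seed = 4)
  expect_equal(m2$sd, 2 * m1$sd)
  expect_equal(m2$mean, 2 * m1$mean)

  # E[1/K] for K ~ N(0.1, 0.005): second-order delta gives 10.025
  set.seed(21)
  kd <- make_param_dist(matrix(rnorm(20000, 0.1, 0.005), ncol = 1,
                               dimnames = list(NULL, "K")))
  mk <- propagate_uncertainty(kd, function(p) 1 / p[["K"]], 1e5, seed = 5)
  expect_equal(mk$mean, 10.025, tolerance = 0.01)
})

test_that("propagation drops non-finite draws and errors when none survive", {
  dist <- make_param_dist(matrix(c(-1, -2, 1), ncol = 1,
                                 dimnames = list(NULL, "K")))
  mc <- propagate_uncertainty(dist, function(p) if (p[["K"]] > 0) 1 / p[["K"]]
                              else NA_real_, n_mc = 300, seed = 2)
  expect_gt(mc$n_dropped, 0)
  expect_equal(mc$mean, 1)
  bad <- make_param_dist(matrix(c(-1, -2), ncol = 1,
                                dimnames = list(NULL, "K")))
  expect_error(
    propagate_uncertainty(bad, function(p) if (p[["K"]] > 0) 1 / p[["K"]]
                          else NA_real_, n_mc = 100, seed = 2),
    class = "caprokin_propagation_error")
})
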