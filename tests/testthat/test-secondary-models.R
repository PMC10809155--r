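# Monod affinity, linear inhibition, rate normalisation and the Welch
# significance screen.

test_that("monod_mu satisfies its identities and shape", {
  expect_equal(monod_mu(0.35, 0.06, 0.35), 0.03)          # S = K_S
  expect_equal(monod_mu(0, 0.06, 0.35), 0)                # no substrate
  expect_equal(monod_mu(6, 0.06, 0.35), 0.0567, tolerance = 1e-3)
  S <- seq(0, 50, by = 0.5)
  mu <- monod_mu(S, 0.06, 0.35)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu < 0.06))
  expect_error(monod_mu(1, 0.06, 0), class = "caprokin_contract_error")
})

test_that("linear_inhibition_mu is a clamped declining line", {
  expect_equal(linear_inhibition_mu(c(0, 5, 50), 0.05, 0), rep(0.05, 3))
  expect_equal(linear_inhibition_mu(13.6, 1, 1 / 13.6), 0)
  expect_equal(linear_inhibition_mu(6, 1, 1 / 13.6), 0.5588, tolerance = 1e-4)
  P <- seq(0, 20, by = 0.5)
  expect_true(all(diff(linear_inhibition_mu(P, 1, 0.08)) <= 0))
  expect_true(all(linear_inhibition_mu(P, 1, 0.2) >= 0))
})

test_that("fit_monod recovers noiseless truth and flags degenerate rates", {
  S <- c(0.05, 0.1, 0.25, 0.5, 1, 2, 4, 6)
  pts <- tibble::tibble(x = S, mu = monod_mu(S, 0.06, 0.35), replicate = "r1")
  fit <- fit_monod(pts, fit_config(n_boot = 0))
  expect_equal(fit$mu_max, 0.06, tolerance = 1e-6)
  expect_equal(fit$K_S, 0.35, tolerance = 1e-6)
  expect_false(fit$ks_at_lower_bound)

  flat <- tibble::tibble(x = S, mu = rep(0.05, length(S)))
  ffit <- fit_monod(flat, fit_config(n_boot = 0))
  expect_true(ffit$ks_at_lower_bound)

  expect_error(fit_monod(tibble::tibble(x = rep(2, 5), mu = 1:5 / 100)),
               class = "caprokin_estimation_error")
})

test_that("fit_monod recovers K_S from a noisy quadruplicate plate design", {
  d <- design_fixture("ks_high_tryptone")
  rates <- simulate_ks_experiment(d, seed = 31)
  fit <- fit_monod(rates[!rates$no_growth, ], fit_config(n_boot = 200, seed = 31))
  expect_equal(fit$K_S, d$K_S, tolerance = 0.2)
  expect_gt(fit$uncertainty$sd[["K_S"]], 0)
})

test_that("rate normalisation maps the baseline to one and is idempotent", {
  pts <- tibble::tibble(
    x = c(0, 0, 0, 0, 4, 4),
    mu = c(0.05, 0.05, 0.05, 0.05, 0.025, 0.025),
    replicate = c("r1", "r2", "r3", "r4", "r1", "r2"))
  n1 <- normalize_rates(pts, 0)
  expect_equal(mean(n1$mu[n1$x == 0]), 1)
  expect_equal(n1$mu[n1$x == 4], c(0.5, 0.5))
  expect_equal(attr(n1, "baseline_mu"), 0.05)
  n2 <- normalize_rates(n1, 0)
  expect_equal(n2$mu, n1$mu, tolerance = 1e-12)
  expect_error(normalize_rates(pts, 99), class = "caprokin_validation_error")
  zero <- tibble::tibble(x = 0, mu = 0)
  expect_error(normalize_rates(zero, 0), class = "caprokin_validation_error")
})

test_that("fit_inhibition recovers the inhibitory concentration exactly on the line", {
  P <- c(0, 2, 4, 6, 8, 10, 12)
  pts <- tibble::tibble(x = P, mu = 1 - P / 13.6)
  fit <- fit_inhibition(pts, fit_config(n_boot = 0))
  expect_equal(fit$mu_max, 1, tolerance = 1e-6)
  expect_equal(fit$P_inhib, 13.6, tolerance = 1e-5)
  # threshold is exactly 1/K at the point estimate
  expect_identical(fit$P_inhib, 1 / fit$K)
})

test_that("fit_inhibition agrees with ordinary least squares on noisy data", {
  set.seed(17)
  P <- rep(c(0, 2, 4, 6, 8, 10), each = 4)
  mu <- 1 - P / 13.6 + rnorm(length(P), 0, 0.03)
  pts <- tibble::tibble(x = P, mu = mu)
  fit <- fit_inhibition(pts, fit_config(n_boot = 0))
  ols <- coef(lm(mu ~ P))   # independent closed-form optimum of the same RMSD
  expect_equal(fit$mu_max, unname(ols[1]), tolerance = 1e-5)
  expect_equal(fit$K, unname(-ols[2] / ols[1]), tolerance = 1e-4)
})

test_that("flat rates give 'not reached' and zero-rate rows are excluded", {
  P <- c(0, 2, 4, 6, 8)
  flat <- tibble::tibble(x = P, mu = rep(1, 5))
  fit <- fit_inhibition(flat, fit_config(n_boot = 0))
  expect_true(fit$not_reached)
  expect_true(is.na(fit$P_inhib))

  withzero <- tibble::tibble(x = c(P, 10, 12), mu = c(1 - P / 8.9, 0, 0),
                             no_growth = c(rep(FALSE, 5), TRUE, TRUE))
  fit2 <- fit_inhibition(withzero, fit_config(n_boot = 0))
  expect_equal(fit2$n_excluded, 2)
  expect_equal(fit2$P_inhib, 8.9, tolerance = 1e-4)
})

test_that("P_inhib uncertainty is propagated and converted to mM", {
  d <- design_fixture("inhibition_lm")
  rates <- normalize_rates(simulate_inhibition_experiment(d, seed = 5), 0)
  fit <- fit_inhibition(rates, fit_config(n_boot = 300, n_mc = 5000, seed = 5))
  expect_equal(fit$P_inhib, 13.6, tolerance = 0.1 * 13.6)
  expect_gt(fit$P_inhib_sd, 0)
  expect_equal(fit$P_inhib_mM, fit$P_inhib * 1000 / 116.16, tolerance = 1e-10)
  expect_equal(fit$P_inhib_mM_sd / fit$P_inhib_sd, 1000 / 116.16,
               tolerance = 1e-10)
})

test_that("welch_test matches the closed-form Welch statistic", {
  a <- c(0.050, 0.052, 0.048)
  b <- c(0.040, 0.041, 0.042)
  got <- welch_test(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_lt(got$p, 0.05)
  expect_true(got$significant)

  # identical groups
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  # degenerate constant groups
  deg <- welch_test(c(1, 1), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)

  expect_error(welch_test(1, c(1, 2)), class = "caprokin_contract_error")
})

test_that("Welch df respects the Welch-Satterthwaite bounds", {
  set.seed(41)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- rnorm(n1); b <- rnorm(n2, 0, runif(1, 0.2, 3))
    df <- welch_test(a, b)$df
    expect_gte(df, min(n1, n2) - 1)
    expect_lte(df, n1 + n2 - 2 + 1e-9)
  }
})

test_that("the significance screen has one row per non-baseline level", {
  d <- design_fixture("inhibition_lm")
  rates <- simulate_inhibition_experiment(d, seed = 9)
  tab <- screen_inhibition_significance(rates, baseline_x = 0)
  expect_equal(nrow(tab), length(setdiff(d$grid, 0)))
  expect_equal(tab$x, sort(setdiff(d$grid, 0)))

  # strongly separated groups are significant everywhere
  sep <- tibble::tibble(
    x = rep(c(0, 2, 4), each = 4),
    mu = c(rnorm(4, 1, 0.01), rnorm(4, 0.5, 0.01), rnorm(4, 0.2, 0.01)))
  st <- screen_inhibition_significance(sep, 0)
  expect_true(all(st$significant))

  # Holm option only tightens
  sh <- screen_inhibition_significance(sep, 0, adjust = "holm")
  expect_true(all(sh$p_adj >= st$p_adj - 1e-15))
})
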