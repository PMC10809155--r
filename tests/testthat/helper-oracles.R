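# Independent oracles and small constructors used across test files.

# Closed-form Welch statistic (textbook formula), independent of t.test().
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Wrap a raw sample matrix as a param_distribution (for propagation tests).
make_param_dist <- function(samples, ci_level = 0.95) {
  samples <- as.matrix(samples)
  structure(
    list(samples = samples,
         mean = apply(samples, 2, mean),
         sd = apply(samples, 2, sd),
         ci_low = apply(samples, 2, quantile, probs = 0.025, names = FALSE),
         ci_high = apply(samples, 2, quantile, probs = 0.975, names = FALSE),
         ci_level = ci_level, seed = 0L, n_boot = nrow(samples), n_failed = 0L),
    class = "param_distribution")
}

# Vectorised RMSD of the Gompertz model over a parameter grid (rows of G),
# used as the brute-force search oracle against the optimizer.
gompertz_grid_rmsd <- function(G, t, y) {
  n <- nrow(G)
  z <- exp(1) * G[, 2] / G[, 1]
  arg <- (G[, 3] %o% rep(1, length(t)) -
            rep(1, n) %o% t) * z + 1
  Y <- G[, 1] * exp(-exp(arg))
  sqrt(rowMeans(sweep(Y, 2, y)^2))
}

# Write a curve set + condition table to temp CSVs in the reader dialect.
write_curve_fixture <- function(curves, conditions, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  curve_path <- file.path(dir, "curves.csv")
  cond_path <- file.path(dir, "conditions.csv")
  write_curves(curves, curve_path)
  readr::write_csv(conditions, cond_path)
  list(curves = curve_path, conditions = cond_path, dir = dir)
}
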