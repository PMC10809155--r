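# Secondary models over condition-level growth rates: Monod substrate
# affinity, linear product inhibition with extrapolated inhibitory
# concentration, baseline normalisation and Welch significance screening.
#
# Rate tables are tibbles with columns x (concentration, g/L), mu (1/h)
# and replicate; optional logical no_growth.

#' Monod growth rate
#'
#' `mu = mu_max * S / (K_S + S)`: increasing in `S`, saturating at
#' `mu_max`, with `mu = mu_max / 2` at `S = K_S`.
#'
#' @param S Substrate concentration (g/L), >= 0.
#' @param mu_max Maximum growth rate (1/h).
#' @param K_S Half-saturation constant (g/L), > 0.
#' @export
monod_mu <- function(S, mu_max, K_S) {
  if (!is_number(K_S) || K_S <= 0) ck_abort("`K_S` must be > 0", "contract")
  if (any(S < 0)) ck_abort("`S` must be >= 0", "contract")
  mu_max * S / (K_S + S)
}

#' Linear product-inhibition growth rate
#'
#' `mu = mu_max * (1 - K * P)`, clamped at zero for prediction: growth
#' stops entirely at `P = 1/K`. `K = 0` means no inhibition.
#'
#' @param P Inhibitor concentration (g/L).
#' @param mu_max Uninhibited rate (1/h, or 1 when rates are normalised).
#' @param K Inhibition slope (L/g), >= 0.
#' @export
linear_inhibition_mu <- function(P, mu_max, K) {
  if (!is_number(K) || K < 0) ck_abort("`K` must be >= 0", "contract")
  mu_max * pmax(0, 1 - K * P)
}

#' Normalise growth rates to a baseline concentration
#'
#' Divides every rate by the mean rate of the replicates measured at
#' `baseline_x` (typically 0 g/L inhibitor), so the baseline maps to 1.
#' Idempotent: renormalising with the same baseline changes nothing.
#'
#' @param points Rate tibble with columns `x`, `mu` (and anything else,
#'   passed through).
#' @param baseline_x Baseline concentration, must be present in `x`.
#' @return The tibble with `mu` rescaled, `normalized = TRUE`, and the
#'   baseline mean stored in attribute `baseline_mu`.
#' @export
normalize_rates <- function(points, baseline_x = 0) {
  base <- points$mu[points$x == baseline_x]
  if (!length(base)) {
    ck_abort(sprintf("no replicates at baseline concentration %g", baseline_x),
             "validation")
  }
  m <- mean(base)
  if (!is.finite(m) || m == 0) {
    ck_abort("baseline mean growth rate is zero; cannot normalise", "validation")
  }
  out <- points
  out$mu <- out$mu / m
  out$normalized <- TRUE
  attr(out, "baseline_mu") <- m
  out
}

#' Fit the Monod model to (substrate, rate) points
#'
#' Estimates `mu_max` and `K_S` by multi-start RMSD minimisation, with
#' case-resampling bootstrap uncertainty stratified by concentration
#' level. A `K_S` estimate collapsing onto its lower bound (rates flat in
#' `S`) is flagged `ks_at_lower_bound`.
#'
#' @param points Rate tibble (`x` = glucose g/L, `mu` = 1/h).
#' @param config A [fit_config()]; `n_boot = 0` skips the bootstrap.
#' @return Object of class `monod_fit`: `mu_max`, `K_S`, `rmsd`,
#'   `uncertainty`, `ks_at_lower_bound`, `n_points`.
#' @export
fit_monod <- function(points, config = fit_config()) {
  x <- points$x
  mu <- points$mu
  if (length(unique(x)) < 3L) {
    ck_abort("Monod fit needs >= 3 distinct substrate concentrations", "estimation")
  }
  mu_max0 <- max(mu)
  if (mu_max0 <= 0) ck_abort("all rates are zero; nothing to fit", "estimation")
  xp <- x[x > 0]
  ks0 <- xp[which.min(abs(mu[x > 0] - mu_max0 / 2))]
  if (!length(ks0) || ks0 == 0) ks0 <- median(xp)
  fac <- c(0.5, 1, 1.5)
  starts <- as.matrix(expand.grid(mu_max = mu_max0 * fac, K_S = ks0 * fac))
  ks_lower <- 1e-6
  lower <- c(1e-8, ks_lower)
  upper <- c(2 * mu_max0, 10 * max(x))
  model <- function(p, xx) p[1] * xx / (p[2] + xx)
  est <- minimize_rmsd(model, x, mu, lower, upper, starts,
                       par_names = c("mu_max", "K_S"),
                       control = list(rel.tol = config$tolerance))
  unc <- NULL
  if (config$n_boot > 0L) {
    unc <- bootstrap_parameters(model, x, mu, est, lower, upper,
                                scheme = "case", strata = x,
                                n_boot = config$n_boot, seed = config$seed,
                                ci_level = config$ci_level)
  }
  ks <- unname(est$values["K_S"])
  structure(
    list(mu_max = unname(est$values["mu_max"]), K_S = ks, rmsd = est$rmsd,
         converged = est$converged, uncertainty = unc,
         ks_at_lower_bound = ks <= ks_lower * 1.01, n_points = length(mu)),
    class = "monod_fit"
  )
}

#' Fit the linear inhibition model and extrapolate the inhibitory concentration
#'
#' Fits `mu = mu_max * (1 - K * P)` (the unclamped line) to measured rates
#' and extrapolates the growth-inhibitory concentration `P_inhib = 1/K`,
#' the concentration at which the line crosses zero. Conditions where no
#' growth occurred are excluded by default — the model describes the
#' decline of measured rates and is extrapolated to zero, and hard zeros
#' would bias the slope; set `include_zero_rates = TRUE` to keep them.
#'
#' Uncertainty of `P_inhib` comes from Monte-Carlo propagation of `1/K`
#' over the bootstrap distribution of `K` (draws with `K <= 0` dropped and
#' counted). If the point estimate of `K` is <= 0 the rates do not decline
#' and `P_inhib` is reported as not reached (`NA`) rather than an error.
#'
#' @param points Rate tibble (`x` = inhibitor g/L, `mu`; optional logical
#'   `no_growth`). Typically normalised first via [normalize_rates()].
#' @param config A [fit_config()].
#' @param include_zero_rates Keep rows with `mu == 0` / `no_growth`?
#' @param compound Registry name used to express `P_inhib` in mM.
#' @param registry Compound registry (see [compound_registry()]).
#' @return Object of class `inhibition_fit`: `mu_max`, `K`, `rmsd`,
#'   `P_inhib` (g/L), `P_inhib_sd`, `P_inhib_mM`, `P_inhib_mM_sd`,
#'   `P_inhib_ci` (g/L), `not_reached`, `uncertainty`, `n_points`.
#' @export
fit_inhibition <- function(points, config = fit_config(),
                           include_zero_rates = FALSE,
                           compound = "caproate",
                           registry = compound_registry()) {
  pts <- points
  if (!include_zero_rates) {
    drop <- pts$mu <= 0
    if ("no_growth" %in% names(pts)) drop <- drop | pts$no_growth
    pts <- pts[!drop, , drop = FALSE]
  }
  x <- pts$x
  mu <- pts$mu
  if (length(unique(x)) < 3L) {
    ck_abort("inhibition fit needs >= 3 distinct inhibitor concentrations",
             "estimation")
  }
  b <- coef(lm(mu ~ x))
  mu_max0 <- max(b[[1]], max(mu) / 2)
  k0 <- -b[[2]] / mu_max0
  fac <- c(0.5, 1, 1.5)
  k_starts <- if (is.finite(k0) && abs(k0) > 1e-8) k0 * fac else c(-0.01, 0.01, 0.1)
  starts <- as.matrix(expand.grid(mu_max = mu_max0 * fac, K = k_starts))
  lower <- c(1e-8, -1)
  upper <- c(2 * max(mu), 10)
  model <- function(p, xx) p[1] * (1 - p[2] * xx)  # unclamped line for fitting
  est <- minimize_rmsd(model, x, mu, lower, upper, starts,
                       par_names = c("mu_max", "K"),
                       control = list(rel.tol = config$tolerance))
  K <- unname(est$values["K"])
  unc <- NULL
  if (config$n_boot > 0L) {
    unc <- bootstrap_parameters(model, x, mu, est, lower, upper,
                                scheme = "case", strata = x,
                                n_boot = config$n_boot, seed = config$seed,
                                ci_level = config$ci_level)
  }
  not_reached <- K <= 0
  p_inhib <- if (not_reached) NA_real_ else 1 / K
  p_sd <- p_mM <- p_mM_sd <- NA_real_
  p_ci <- c(NA_real_, NA_real_)
  if (!not_reached && !is.null(unc)) {
    mc <- propagate_uncertainty(
      unc, function(p) if (p[["K"]] > 0) 1 / p[["K"]] else NA_real_,
      n_mc = config$n_mc, seed = config$seed + 1L, ci_level = config$ci_level)
    p_sd <- mc$sd
    p_ci <- c(mc$ci_low, mc$ci_high)
  }
  if (!not_reached) {
    p_mM <- gl_to_mM(p_inhib, compound, registry)
    cmp <- find_compound(compound, registry)
    if (is.finite(p_sd)) p_mM_sd <- p_sd * 1000 / cmp$molar_mass
  }
  structure(
    list(mu_max = unname(est$values["mu_max"]), K = K, rmsd = est$rmsd,
         converged = est$converged, uncertainty = unc,
         P_inhib = p_inhib, P_inhib_sd = p_sd, P_inhib_ci = p_ci,
         P_inhib_mM = p_mM, P_inhib_mM_sd = p_mM_sd,
         not_reached = not_reached, n_points = length(mu),
         n_excluded = nrow(points) - length(mu)),
    class = "inhibition_fit"
  )
}

#' Welch's unequal-variances t-test between two groups of rates
#'
#' Two-sided Welch test with Welch–Satterthwaite degrees of freedom.
#' Degenerate zero-variance cases (possible with deterministic synthetic
#' rates) are resolved before delegating to [stats::t.test()]: equal
#' constant groups give t = 0, p = 1; different constant groups give
#' p = 0 with `degenerate = TRUE`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param alpha Significance level.
#' @return One-row tibble: `t`, `df`, `p`, `significant`, `degenerate`.
#' @export
welch_test <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    ck_abort("each group needs >= 2 observations", "contract")
  }
  va <- sd(group_a)^2
  vb <- sd(group_b)^2
  if (va == 0 && vb == 0) {
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(tibble::tibble(
      t = if (same) 0 else sign(mean(group_a) - mean(group_b)) * Inf,
      df = length(group_a) + length(group_b) - 2,
      p = if (same) 1 else 0,
      significant = !same && 0 < alpha,
      degenerate = TRUE))
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, significant = ht$p.value < alpha,
                 degenerate = FALSE)
}

#' Screen each inhibitor concentration against the baseline rate
#'
#' One Welch test per non-baseline concentration, comparing replicate
#' rates at that level with the replicate rates at `baseline_x` (the
#' 0 g/L condition). No multiple-testing correction by default (pairwise
#' reporting convention); `adjust = "holm"` is available.
#'
#' @param points Rate tibble (`x`, `mu`, `replicate`).
#' @param baseline_x Baseline concentration.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return Tibble with one row per non-baseline concentration: `x`,
#'   `mu_mean`, `n`, `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
screen_inhibition_significance <- function(points, baseline_x = 0,
                                           alpha = 0.05, adjust = "none") {
  base <- points$mu[points$x == baseline_x]
  if (length(base) < 2L) {
    ck_abort(sprintf("need >= 2 baseline replicates at x = %g", baseline_x),
             "validation")
  }
  levels_x <- sort(setdiff(unique(points$x), baseline_x))
  rows <- lapply(levels_x, function(xv) {
    g <- points$mu[points$x == xv]
    wt <- welch_test(g, base, alpha = alpha)
    tibble::tibble(x = xv, mu_mean = mean(g), n = length(g),
                   t = wt$t, df = wt$df, p = wt$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p_adj < alpha
  out
}

#' @export
print.monod_fit <- function(x, ...) {
  cat(sprintf("<monod_fit> mu_max = %.4g 1/h, K_S = %.4g g/L (rmsd %.3g, n %d)\n",
              x$mu_max, x$K_S, x$rmsd, x$n_points))
  if (x$ks_at_lower_bound) cat("  note: K_S collapsed to its lower bound (rates flat in S)\n")
  invisible(x)
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("<inhibition_fit> mu_max = %.4g, K = %.4g L/g (rmsd %.3g, n %d)\n",
              x$mu_max, x$K, x$rmsd, x$n_points))
  if (x$not_reached) {
    cat("  inhibitory concentration not reached (K <= 0)\n")
  } else {
    cat(sprintf("  P_inhib = %.3g +/- %.2g g/L (%.3g +/- %.2g mM)\n",
                x$P_inhib, x$P_inhib_sd, x$P_inhib_mM, x$P_inhib_mM_sd))
  }
  invisible(x)
}
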