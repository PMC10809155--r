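# Primary growth model: the modified Gompertz equation in the Zwietering
# parameterisation, fitted per replicate curve.

#' Modified Gompertz growth curve
#'
#' Evaluates the sigmoid
#' \deqn{y(t) = A \exp\!\left(-\exp\!\left(\frac{\mu_m e}{A}(\lambda - t) + 1\right)\right)}
#' where `A` is the maximum normalised growth (asymptote), `mu_m` the
#' maximum specific growth rate (the maximal slope of `y(t)`, in 1/h when
#' `t` is in hours and `y` is log-normalised signal), and `lam` the lag
#' time (h). The curve is non-decreasing in `t` and bounded by `A`; at
#' `t = lam` it equals `A exp(-e)`.
#'
#' @param t Time (h), any numeric vector.
#' @param A Asymptote, > 0.
#' @param mu_m Maximum specific growth rate, >= 0.
#' @param lam Lag time (h).
#' @return Numeric vector of model values.
#' @examples
#' gompertz_curve(c(0, 10, 50, 200), A = 1.5, mu_m = 0.05, lam = 8)
#' @export
gompertz_curve <- function(t, A, mu_m, lam) {
  if (!is_number(A) || A <= 0) ck_abort("`A` must be a positive number", "contract")
  if (!is_number(mu_m) || mu_m < 0) ck_abort("`mu_m` must be non-negative", "contract")
  if (any(!is.finite(t))) ck_abort("`t` must be finite", "contract")
  A * exp(-exp(mu_m * exp(1) / A * (lam - t) + 1))
}

#' Fit the modified Gompertz model to one normalised growth curve
#'
#' Estimates (A, mu_m, lam) by multi-start RMSD minimisation and attaches
#' bootstrap uncertainty (residual resampling). Curves whose normalised
#' signal never rises above `config$growth_threshold` are flagged
#' `no_growth` and carry no parameters.
#'
#' Start values are data-driven: `A0 = max(y)`, `mu0` the steepest
#' finite-difference slope, `lam0` the intercept of the max-slope tangent
#' with y = 0 (clamped to >= 0); the start grid perturbs each by +/- 50%.
#' Bounds: A in (0, 2 max(y)], mu_m in (0, 10 mu0], lam in [0, max(t)].
#'
#' @param curve A `normalized_curve` (see [normalize()]) or any list with
#'   numeric `times` and `y` of equal length >= 5.
#' @param config A [fit_config()]. Set `n_boot = 0` to skip the bootstrap.
#' @return Object of class `gompertz_fit` with fields `A`, `mu_m`, `lam`,
#'   `rmsd`, `converged`, `uncertainty` (a `param_distribution` or NULL),
#'   `no_growth`, `n_points`, and the curve's ids.
#' @export
fit_gompertz <- function(curve, config = fit_config()) {
  t <- curve$times
  y <- curve$y
  if (identical(curve$mode, "linear")) y <- y - 1  # growth increment above start
  if (length(t) < 5L || length(y) != length(t)) {
    ck_abort("a growth curve needs >= 5 (time, y) points", "contract")
  }
  ids <- list(replicate_id = curve$replicate_id %||% NA_character_,
              condition_id = curve$condition_id %||% NA_character_)

  if (max(y) < config$growth_threshold) {
    return(structure(
      c(list(A = NA_real_, mu_m = NA_real_, lam = NA_real_, rmsd = NA_real_,
             converged = NA, uncertainty = NULL, no_growth = TRUE,
             n_points = length(y)), ids),
      class = "gompertz_fit"
    ))
  }

  slopes <- diff(y) / diff(t)
  k <- which.max(slopes)
  mu0 <- max(slopes[k], 1e-6)
  A0 <- max(y)
  t_mid <- (t[k] + t[k + 1]) / 2
  y_mid <- (y[k] + y[k + 1]) / 2
  lam0 <- max(0, t_mid - y_mid / mu0)

  fac <- c(0.5, 1, 1.5)
  starts <- as.matrix(expand.grid(A = A0 * fac, mu_m = mu0 * fac,
                                  lam = pmax(lam0, 1e-3) * fac))
  lower <- c(1e-8, 1e-8, 0)
  upper <- c(2 * A0, 10 * mu0, max(t))
  model <- function(p, tt) gompertz_curve(tt, p[1], p[2], p[3])

  est <- minimize_rmsd(model, t, y, lower, upper, starts,
                       par_names = c("A", "mu_m", "lam"),
                       control = list(rel.tol = config$tolerance,
                                      iter.max = config$max_iterations))
  unc <- NULL
  if (config$n_boot > 0L) {
    unc <- bootstrap_parameters(model, t, y, est, lower, upper,
                                scheme = "residual", n_boot = config$n_boot,
                                seed = config$seed, ci_level = config$ci_level)
  }
  structure(
    c(list(A = unname(est$values["A"]), mu_m = unname(est$values["mu_m"]),
           lam = unname(est$values["lam"]), rmsd = est$rmsd,
           converged = est$converged, uncertainty = unc, no_growth = FALSE,
           n_points = est$n_points), ids),
    class = "gompertz_fit"
  )
}

#' Aggregate replicate Gompertz fits into a condition-level growth rate
#'
#' Arithmetic mean and sample standard deviation of the replicate `mu_m`
#' values; `no_growth` replicates are excluded and counted. When every
#' replicate is `no_growth`, the condition itself is flagged `no_growth`
#' with an `NA` rate.
#'
#' @param fits List of `gompertz_fit` objects for one condition.
#' @return One-row tibble: `mu_mean`, `mu_sd`, `n`, `n_no_growth`,
#'   `no_growth`, plus mean `A` and `lam` of the growing replicates.
#' @export
summarize_condition <- function(fits) {
  if (!length(fits)) ck_abort("no fits supplied", "contract")
  if (inherits(fits, "gompertz_fit")) fits <- list(fits)
  ng <- vapply(fits, function(f) isTRUE(f$no_growth), logical(1))
  grown <- fits[!ng]
  if (!length(grown)) {
    return(tibble::tibble(mu_mean = NA_real_, mu_sd = NA_real_, n = 0L,
                          n_no_growth = sum(ng), no_growth = TRUE,
                          A_mean = NA_real_, lam_mean = NA_real_))
  }
  mu <- vapply(grown, `[[`, numeric(1), "mu_m")
  tibble::tibble(
    mu_mean = mean(mu),
    mu_sd = if (length(mu) > 1L) sd(mu) else NA_real_,
    n = length(mu),
    n_no_growth = sum(ng),
    no_growth = FALSE,
    A_mean = mean(vapply(grown, `[[`, numeric(1), "A")),
    lam_mean = mean(vapply(grown, `[[`, numeric(1), "lam"))
  )
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (isTRUE(x$no_growth)) {
    cat("<gompertz_fit> no growth detected\n")
    return(invisible(x))
  }
  cat(sprintf("<gompertz_fit> A = %.4g, mu_m = %.4g 1/h, lam = %.4g h (rmsd %.3g, n %d)\n",
              x$A, x$mu_m, x$lam, x$rmsd, x$n_points))
  if (!is.null(x$uncertainty)) {
    s <- x$uncertainty
    cat(sprintf("  bootstrap (n=%d): mu_m %.4g +/- %.2g [%.4g, %.4g]\n",
                nrow(s$samples), s$mean["mu_m"], s$sd["mu_m"],
                s$ci_low["mu_m"], s$ci_high["mu_m"]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
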