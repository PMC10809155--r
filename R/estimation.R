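# Shared fitting engine: RMSD objective, deterministic multi-start bounded
# minimisation, bootstrap parameter uncertainty, Monte-Carlo propagation.

#' Root-mean-squared deviation between observed and predicted values
#'
#' The objective minimised by every model fit in the package:
#' \code{sqrt(mean((predicted - observed)^2))}. The minimiser location is
#' identical to that of the plain sum of squares; reported values follow
#' this root-mean definition so they are on the scale of the data.
#'
#' @param observed Numeric vector of observations.
#' @param predicted Numeric vector of model predictions, same length.
#' @return A single non-negative number.
#' @examples
#' rmsd(c(0, 0), c(3, 4)) # sqrt(25/2)
#' @export
rmsd <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    ck_abort("`observed` and `predicted` must have the same length", "contract")
  }
  if (length(observed) < 1L) {
    ck_abort("`observed` must contain at least one value", "contract")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Fit configuration
#'
#' Bundles the knobs shared by all fitting operations. `seed` is mandatory:
#' every stochastic step (bootstrap resampling, Monte-Carlo propagation)
#' derives its stream from it, so identical configs give identical results.
#'
#' @param n_boot Number of bootstrap refits (default 1000).
#' @param n_mc Number of Monte-Carlo draws for derived quantities (default 10000).
#' @param seed Integer master seed (default 1291007).
#' @param ci_level Two-sided confidence level for percentile intervals (default 0.95).
#' @param max_iterations Iteration cap for the local minimiser.
#' @param tolerance Relative convergence tolerance for the local minimiser.
#' @param growth_threshold Minimum rise of the normalised signal (log units)
#'   below which a curve is flagged `no_growth` (default 0.05, about a 5%
#'   signal increase).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_boot = 1000L, n_mc = 10000L, seed = 1291007L,
                       ci_level = 0.95, max_iterations = 500L,
                       tolerance = 1e-12, growth_threshold = 0.05) {
  if (is.null(seed)) ck_abort("fit configuration requires a `seed`", "config")
  if (!is_number(ci_level) || ci_level <= 0 || ci_level >= 1) {
    ck_abort("`ci_level` must be in (0, 1)", "config")
  }
  structure(
    list(n_boot = as.integer(n_boot), n_mc = as.integer(n_mc),
         seed = as.integer(seed), ci_level = ci_level,
         max_iterations = as.integer(max_iterations), tolerance = tolerance,
         growth_threshold = growth_threshold),
    class = "fit_config"
  )
}

#' Minimise the RMSD of a parametric model by deterministic multi-start search
#'
#' Runs a bounded local minimisation (`stats::nlminb`) from every row of a
#' start grid and keeps the best result. Given identical inputs the result
#' is identical: no randomness is involved, and exact RMSD ties are broken
#' by the lexicographically smallest parameter vector.
#'
#' @param model Function `model(params, x)` returning predictions.
#' @param x Predictor values (passed through to `model`).
#' @param y Numeric response vector.
#' @param lower,upper Finite per-parameter bounds.
#' @param starts Numeric matrix of initial parameter vectors (one per row),
#'   or a single numeric vector. Starts are clamped into the bounds.
#' @param par_names Optional parameter labels.
#' @param control Optional list overriding `nlminb` control settings.
#' @return An object of class `param_estimate`: list with `names`, `values`
#'   (named vector), `rmsd`, `converged`, `n_points`, `n_starts_failed`.
#' @export
minimize_rmsd <- function(model, x, y, lower, upper, starts,
                          par_names = NULL, control = list()) {
  if (is.null(dim(starts))) starts <- matrix(starts, nrow = 1L)
  n_par <- ncol(starts)
  if (length(lower) != n_par || length(upper) != n_par) {
    ck_abort("`lower`/`upper` must match the number of parameters", "contract")
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    ck_abort("parameter bounds must be finite", "contract")
  }
  if (length(y) < n_par) {
    ck_abort("need at least as many data points as parameters", "contract")
  }
  if (is.null(par_names)) par_names <- paste0("p", seq_len(n_par))

  objective <- function(p) {
    pred <- model(p, x)
    if (any(!is.finite(pred))) return(.Machine$double.xmax)
    rmsd(y, pred)
  }
  ctrl <- modifyList(list(iter.max = 500L, eval.max = 1000L,
                          rel.tol = 1e-12, x.tol = 1.5e-10), control)

  best_val <- Inf
  best_par <- NULL
  best_start_obj <- Inf
  n_failed <- 0L
  diagnostics <- character()
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[i, ], lower), upper)
    best_start_obj <- min(best_start_obj, objective(p0))
    res <- tryCatch(
      nlminb(p0, objective, lower = lower, upper = upper, control = ctrl),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      diagnostics <- c(diagnostics, conditionMessage(res))
      next
    }
    val <- res$objective
    if (!is.finite(val)) {
      n_failed <- n_failed + 1L
      next
    }
    take <- val < best_val - 1e-15 ||
      (abs(val - best_val) <= 1e-15 && !is.null(best_par) &&
         lex_less(res$par, best_par))
    if (is.null(best_par) || take) {
      best_val <- val
      best_par <- res$par
    }
  }
  if (is.null(best_par)) {
    ck_abort(paste0("all optimisation starts failed: ",
                    paste(unique(diagnostics), collapse = "; ")),
             "estimation")
  }
  values <- setNames(best_par, par_names)
  structure(
    list(names = par_names, values = values, rmsd = best_val,
         converged = best_val <= best_start_obj + 1e-12,
         n_points = length(y), n_starts_failed = n_failed),
    class = "param_estimate"
  )
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Bootstrap uncertainty of fitted parameters
#'
#' Refits the model on `n_boot` resampled datasets and summarises the
#' resulting parameter cloud. Two schemes are provided, matching the two
#' data shapes in the pipeline:
#' \describe{
#'   \item{`residual`}{time-series fits (Gompertz curves): resample the
#'     residuals of the base fit with replacement and refit on
#'     `fitted + resampled residuals`.}
#'   \item{`case`}{rate-table fits (Monod, inhibition): resample data
#'     points with replacement, stratified by `strata` (typically the
#'     concentration level) so every level stays represented.}
#' }
#' Refits start from the base point estimate. With more than 50% refit
#' failures an estimation error is raised; otherwise failures are counted
#' and summaries use the successful refits.
#'
#' @param model,x,y,lower,upper As in [minimize_rmsd()].
#' @param estimate The base `param_estimate` (must have converged).
#' @param scheme `"residual"` or `"case"`.
#' @param strata Optional stratification vector for case resampling.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param ci_level Percentile interval level.
#' @return Object of class `param_distribution`: `samples` matrix
#'   (successful refits by parameter), per-parameter `mean`, `sd`,
#'   `ci_low`, `ci_high`, plus `seed`, `n_boot`, `n_failed`.
#' @export
bootstrap_parameters <- function(model, x, y, estimate, lower, upper,
                                 scheme = c("residual", "case"),
                                 strata = NULL, n_boot = 1000L,
                                 seed = 1291007L, ci_level = 0.95) {
  scheme <- match.arg(scheme)
  if (!inherits(estimate, "param_estimate") || !isTRUE(estimate$converged)) {
    ck_abort("bootstrap requires a converged base fit", "estimation")
  }
  n_boot <- as.integer(n_boot)
  if (n_boot < 2L) ck_abort("`n_boot` must be at least 2", "contract")
  p_hat <- unname(estimate$values)
  fitted_base <- model(p_hat, x)
  resid_base <- y - fitted_base
  m <- length(y)
  if (scheme == "case" && is.null(strata)) strata <- rep(1L, m)

  objective_for <- function(y_star, x_star) {
    function(p) {
      pred <- model(p, x_star)
      if (any(!is.finite(pred))) return(.Machine$double.xmax)
      rmsd(y_star, pred)
    }
  }
  ctrl <- list(iter.max = 300L, eval.max = 600L, rel.tol = 1e-12)

  samples <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = length(p_hat))
    for (b in seq_len(n_boot)) {
      if (scheme == "residual") {
        idx <- sample.int(m, m, replace = TRUE)
        y_b <- fitted_base + resid_base[idx]
        x_b <- x
      } else {
        idx <- unlist(lapply(split(seq_len(m), strata), function(ii) {
          ii[sample.int(length(ii), length(ii), replace = TRUE)]
        }), use.names = FALSE)
        y_b <- y[idx]
        x_b <- x[idx]
      }
      res <- tryCatch(
        nlminb(p_hat, objective_for(y_b, x_b),
               lower = lower, upper = upper, control = ctrl),
        error = function(e) NULL
      )
      if (!is.null(res) && is.finite(res$objective)) out[b, ] <- res$par
    }
    out
  })

  ok <- stats::complete.cases(samples)
  n_failed <- sum(!ok)
  if (n_failed > n_boot / 2) {
    ck_abort(sprintf("bootstrap failed: %d of %d refits did not converge",
                     n_failed, n_boot), "estimation")
  }
  samples <- samples[ok, , drop = FALSE]
  colnames(samples) <- estimate$names
  alpha <- (1 - ci_level) / 2
  structure(
    list(samples = samples,
         mean = apply(samples, 2, mean),
         sd = apply(samples, 2, sd),
         ci_low = apply(samples, 2, quantile, probs = alpha, names = FALSE),
         ci_high = apply(samples, 2, quantile, probs = 1 - alpha, names = FALSE),
         ci_level = ci_level, seed = as.integer(seed),
         n_boot = n_boot, n_failed = n_failed),
    class = "param_distribution"
  )
}

#' Monte-Carlo propagation of a derived quantity
#'
#' Draws parameter vectors from a bootstrap distribution (resampling rows
#' of the sample matrix with replacement), evaluates a derived quantity on
#' each draw, and summarises it. Non-finite evaluations (e.g. 1/K when a
#' draw has K <= 0) are dropped and counted.
#'
#' @param dist A `param_distribution` from [bootstrap_parameters()].
#' @param derived Function taking a named parameter vector, returning a
#'   single number (may be `NA`/non-finite for invalid draws).
#' @param n_mc Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @param ci_level Percentile interval level (defaults to the distribution's).
#' @return List of class `mc_summary`: `mean`, `sd`, `ci_low`, `ci_high`,
#'   `n_mc`, `n_dropped`, `seed`.
#' @export
propagate_uncertainty <- function(dist, derived, n_mc = 10000L,
                                  seed = 1291007L, ci_level = NULL) {
  if (!inherits(dist, "param_distribution")) {
    ck_abort("`dist` must be a param_distribution", "contract")
  }
  if (is.null(ci_level)) ci_level <- dist$ci_level
  n_mc <- as.integer(n_mc)
  n_row <- nrow(dist$samples)
  draws <- with_seed(seed, {
    idx <- sample.int(n_row, n_mc, replace = TRUE)
    vapply(idx, function(i) {
      v <- tryCatch(derived(dist$samples[i, ]), error = function(e) NA_real_)
      if (length(v) != 1L || !is.numeric(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  })
  keep <- is.finite(draws)
  if (!any(keep)) {
    ck_abort("all Monte-Carlo draws of the derived quantity were non-finite",
             "propagation")
  }
  draws <- draws[keep]
  alpha <- (1 - ci_level) / 2
  structure(
    list(mean = mean(draws), sd = sd(draws),
         ci_low = quantile(draws, alpha, names = FALSE),
         ci_high = quantile(draws, 1 - alpha, names = FALSE),
         n_mc = n_mc, n_dropped = sum(!keep), seed = as.integer(seed),
         ci_level = ci_level),
    class = "mc_summary"
  )
}

#' @export
print.param_estimate <- function(x, ...) {
  cat("<param_estimate>", if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(signif(x$values, 6))
  cat("rmsd:", signif(x$rmsd, 6), " n:", x$n_points, "\n")
  invisible(x)
}

#' @export
print.param_distribution <- function(x, ...) {
  cat(sprintf("<param_distribution> %d bootstrap samples (%d failed), seed %d\n",
              nrow(x$samples), x$n_failed, x$seed))
  tab <- rbind(mean = x$mean, sd = x$sd, ci_low = x$ci_low, ci_high = x$ci_high)
  print(signif(tab, 5))
  invisible(x)
}
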