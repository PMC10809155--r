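# Synthetic-data generators emulating the serum-bottle growth, 96-well
# substrate-affinity (K_S) and 96-well caproate-inhibition experiments,
# plus balanced fermentation stoichiometries for the electron ledger.
#
# Every generator is a pure function of (design, seed): the caller's RNG
# state is untouched and a fixed seed reproduces the dataset bit for bit.

#' Named experimental design fixtures
#'
#' Ready-made designs mirroring the package's reference experiments:
#' \describe{
#'   \item{`serum_bottle_growth`}{triplicate serum bottles, 2 g/L glucose:
#'     Gompertz truth A = 1.5 (log units), mu_m = 0.051 1/h, lam = 8 h,
#'     61 samples over 120 h, noise sd 0.02 log units.}
#'   \item{`ks_high_tryptone`}{glucose affinity plate, quadruplicates on
#'     glucose 0–6 g/L (levels 0, 0.05, 0.1, 0.25, 0.5, 1, 2, 4, 6);
#'     Monod truth mu_max = 0.06 1/h, K_S = 0.35 g/L; 5% relative noise.}
#'   \item{`inhibition_lm`}{caproate inhibition plate for the
#'     reactor-derived lactobacillus: levels 0, 2, 4, 6, 7, 8, 9, 10, 11,
#'     12 g/L, quadruplicates, truth mu_max = 0.051 1/h,
#'     K = 1/13.6 L/g; 5% relative noise.}
#'   \item{`inhibition_lr`}{inhibition plate for the non-adapted type
#'     strain: levels 0, 1, 2, 3, 4, 5, 6, 8, 10, 12 g/L, quadruplicates,
#'     truth mu_max = 0.05 1/h, K = 1/8.9 L/g (so 10 and 12 g/L exceed
#'     the inhibitory threshold and yield no growth); 5% relative noise.}
#' }
#'
#' @param name Fixture name.
#' @return A design list for the matching `simulate_*` generator.
#' @export
design_fixture <- function(name = c("serum_bottle_growth", "ks_high_tryptone",
                                    "inhibition_lm", "inhibition_lr")) {
  name <- match.arg(name)
  switch(name,
    serum_bottle_growth = list(
      A = 1.5, mu_m = 0.051, lam = 8,
      times = seq(0, 120, length.out = 61),
      noise_sd = 0.02, n_replicates = 3L, signal0 = 100,
      condition_id = "serum_bottle_growth"),
    ks_high_tryptone = list(
      mu_max = 0.06, K_S = 0.35,
      grid = c(0, 0.05, 0.1, 0.25, 0.5, 1, 2, 4, 6),
      n_replicates = 4L, noise_sd_rel = 0.05),
    inhibition_lm = list(
      mu_max = 0.051, K = 1 / 13.6,
      grid = c(0, 2, 4, 6, 7, 8, 9, 10, 11, 12),
      n_replicates = 4L, noise_sd_rel = 0.05),
    inhibition_lr = list(
      mu_max = 0.05, K = 1 / 8.9,
      grid = c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12),
      n_replicates = 4L, noise_sd_rel = 0.05)
  )
}

#' Simulate replicated Gompertz growth curves
#'
#' Draws `y(t) = gompertz_curve(t) + N(0, noise_sd)` per point on the
#' log-normalised scale and back-transforms to a raw signal
#' `signal = signal0 * exp(y)`, i.e. multiplicative instrument noise.
#' Replicates get independent noise from one master seed.
#'
#' @param design List with `A`, `mu_m`, `lam`, `times`, and optionally
#'   `noise_sd` (default 0.02), `n_replicates` (1), `signal0` (100),
#'   `condition_id`, `meta`.
#' @param seed Integer seed.
#' @return List of [growth_curve()] objects (replicates `r1`, `r2`, ...).
#' @export
simulate_growth_curve <- function(design, seed = 1L) {
  d <- design
  noise_sd <- d$noise_sd %||% 0.02
  n_rep <- d$n_replicates %||% 1L
  signal0 <- d$signal0 %||% 100
  cid <- d$condition_id %||% "sim"
  if (noise_sd < 0 || n_rep < 1L) ck_abort("invalid design", "contract")
  y_true <- gompertz_curve(d$times, d$A, d$mu_m, d$lam)
  with_seed(seed, {
    lapply(seq_len(n_rep), function(r) {
      y <- y_true + rnorm(length(y_true), 0, noise_sd)
      growth_curve(d$times, signal0 * exp(y),
                   replicate_id = paste0("r", r), condition_id = cid,
                   meta = d$meta %||% list(truth = d[c("A", "mu_m", "lam")]))
    })
  })
}

#' Simulate a glucose half-saturation (K_S) plate experiment
#'
#' Per glucose level and replicate, the true rate comes from the Monod
#' curve; measured rates get relative Gaussian noise (truncated at 0).
#' The 0 g/L level yields no growth (mu = 0, `no_growth = TRUE`). With
#' `output = "curves"` full Gompertz curves are generated instead, with
#' `mu_m` set by the Monod truth at each level.
#'
#' @param design List with `mu_max`, `K_S`, `grid`, `n_replicates`,
#'   `noise_sd_rel`; see [design_fixture()]`("ks_high_tryptone")`.
#' @param seed Integer seed.
#' @param output `"rates"` (tibble `x`, `mu`, `replicate`, `no_growth`) or
#'   `"curves"` (list of growth_curve).
#' @export
simulate_ks_experiment <- function(design, seed = 1L,
                                   output = c("rates", "curves")) {
  output <- match.arg(output)
  d <- design
  if (min(d$grid) >= d$K_S || max(d$grid) <= d$K_S) {
    ck_abort("the glucose grid must span concentrations below and above K_S",
             "contract")
  }
  mu_true <- monod_mu(d$grid, d$mu_max, d$K_S)
  sim_rate_table(d$grid, mu_true, d$n_replicates, d$noise_sd_rel, seed,
                 output = output, curve_design = d)
}

#' Simulate a caproate inhibition plate experiment
#'
#' Per caproate level and replicate, the true rate follows the linear
#' inhibition model; levels at or beyond the inhibitory threshold
#' (`1 - K * P <= 0`) produce `no_growth` replicates with mu = 0.
#' Optionally the lag time inflates with the inhibitor
#' (`lam = lag_base * (1 + lag_slope * P)`) when curves are generated,
#' emulating the longer lag phases seen at high caproate.
#'
#' @param design List with `mu_max`, `K`, `grid` (must include 0 for the
#'   baseline), `n_replicates`, `noise_sd_rel`, optionally `lag_base`,
#'   `lag_slope`; see [design_fixture()]`("inhibition_lm")`.
#' @param seed Integer seed.
#' @param output `"rates"` or `"curves"`.
#' @export
simulate_inhibition_experiment <- function(design, seed = 1L,
                                           output = c("rates", "curves")) {
  output <- match.arg(output)
  d <- design
  if (!0 %in% d$grid) ck_abort("the inhibitor grid must include the 0 g/L baseline",
                               "contract")
  mu_true <- linear_inhibition_mu(d$grid, d$mu_max, d$K)
  sim_rate_table(d$grid, mu_true, d$n_replicates, d$noise_sd_rel, seed,
                 output = output, curve_design = d, inhibitor = TRUE)
}

# Shared rate-table / curve-set generator for the two plate experiments.
sim_rate_table <- function(grid, mu_true, n_rep, noise_rel, seed,
                           output, curve_design, inhibitor = FALSE) {
  with_seed(seed, {
    if (output == "rates") {
      rows <- lapply(seq_along(grid), function(i) {
        grows <- mu_true[i] > 0
        mu <- if (grows) pmax(0, mu_true[i] * (1 + rnorm(n_rep, 0, noise_rel)))
              else rep(0, n_rep)
        tibble::tibble(x = grid[i], mu = mu,
                       replicate = paste0("r", seq_len(n_rep)),
                       no_growth = !grows)
      })
      out <- dplyr::bind_rows(rows)
      attr(out, "noise_model") <- "relative gaussian on mu"
      out
    } else {
      d <- curve_design
      A <- d$A %||% 1.5
      times <- d$times %||% seq(0, 200, length.out = 60)
      noise_sd <- d$noise_sd %||% 0.02
      signal0 <- d$signal0 %||% 100
      lag_base <- d$lag_base %||% 8
      lag_slope <- d$lag_slope %||% 0
      out <- list()
      for (i in seq_along(grid)) {
        lam <- if (inhibitor) lag_base * (1 + lag_slope * grid[i]) else lag_base
        for (r in seq_len(n_rep)) {
          y <- if (mu_true[i] > 0) {
            gompertz_curve(times, A, mu_true[i], lam) +
              rnorm(length(times), 0, noise_sd)
          } else {
            rnorm(length(times), 0, noise_sd)  # flat no-growth well
          }
          out[[length(out) + 1L]] <- growth_curve(
            times, signal0 * exp(y), replicate_id = paste0("r", r),
            condition_id = sprintf("x%g", grid[i]),
            meta = list(x = grid[i], mu_true = mu_true[i]))
        }
      }
      out
    }
  })
}

#' Reference fermentation stoichiometries
#'
#' Balanced reactions (coefficients in mol) used by the electron-balance
#' machinery and its tests: homolactic (glucose to 2 lactate),
#' heterolactic (glucose to lactate + ethanol + CO2), and glucose
#' chain elongation to caproate (1.5 glucose to 1 caproate + 3 CO2 +
#' 2 H2 + 1 H2O).
#'
#' @param name Reaction name.
#' @return Tibble with `compound`, `coeff` (mol, positive), `role`.
#' @export
reaction_fixture <- function(name = c("homolactic", "heterolactic",
                                      "chain_elongation")) {
  name <- match.arg(name)
  switch(name,
    homolactic = tibble::tibble(
      compound = c("glucose", "lactate"),
      coeff = c(1, 2),
      role = c("substrate", "product")),
    heterolactic = tibble::tibble(
      compound = c("glucose", "lactate", "ethanol", "carbon dioxide"),
      coeff = c(1, 1, 1, 1),
      role = c("substrate", "product", "product", "gas")),
    chain_elongation = tibble::tibble(
      compound = c("glucose", "caproate", "carbon dioxide", "hydrogen", "water"),
      coeff = c(1.5, 1, 3, 2, 1),
      role = c("substrate", "product", "gas", "gas", "product"))
  )
}

#' Simulate a mass-balance dataset from a balanced stoichiometry
#'
#' Scales a balanced reaction by an extent (mol/L) into concentration
#' changes in g/L (substrates negative), optionally perturbed by relative
#' measurement noise. The reaction is checked to be electron-balanced at
#' generation time; an unbalanced one is rejected.
#'
#' @param stoichiometry Tibble as from [reaction_fixture()].
#' @param extent Reaction extent in mol/L, > 0.
#' @param noise_sd_rel Relative sd of measurement noise on each delta.
#' @param seed Integer seed (used only when `noise_sd_rel > 0`).
#' @param registry A [compound_registry()].
#' @return Tibble of balance entries (`compound`, `delta_g_l`, `role`)
#'   ready for [electron_balance()].
#' @export
simulate_balance_dataset <- function(stoichiometry, extent, noise_sd_rel = 0,
                                     seed = 1L,
                                     registry = compound_registry()) {
  if (!is_number(extent) || extent <= 0) {
    ck_abort("`extent` must be a positive number (mol/L)", "contract")
  }
  e <- vapply(stoichiometry$compound, function(nm)
    find_compound(nm, registry)$electrons_per_mol, numeric(1))
  e_in <- sum(stoichiometry$coeff[stoichiometry$role == "substrate"] *
                e[stoichiometry$role == "substrate"])
  e_out <- sum(stoichiometry$coeff[stoichiometry$role != "substrate"] *
                 e[stoichiometry$role != "substrate"])
  if (abs(e_in - e_out) > 1e-6 * max(e_in, 1)) {
    ck_abort(sprintf(
      "stoichiometry is not electron-balanced: %.4g e- in vs %.4g e- out",
      e_in, e_out), "validation")
  }
  mm <- vapply(stoichiometry$compound, function(nm)
    find_compound(nm, registry)$molar_mass, numeric(1))
  sign <- ifelse(stoichiometry$role == "substrate", -1, 1)
  delta <- sign * stoichiometry$coeff * extent * mm
  if (noise_sd_rel > 0) {
    delta <- with_seed(seed,
      delta * (1 + rnorm(length(delta), 0, noise_sd_rel)))
  }
  tibble::tibble(compound = stoichiometry$compound, delta_g_l = delta,
                 role = stoichiometry$role)
}
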