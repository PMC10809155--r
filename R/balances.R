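# Biomass bookkeeping: VSS concentration, biomass yield on glucose, and
# degree-of-reduction electron balances over fermentation products.

#' Volatile suspended solids concentration
#'
#' VSS is the biomass proxy of Standard Methods 2540E: the mass lost
#' between drying (105 C, `mass_dried` = m1) and ignition (550 C,
#' `mass_ashed` = m2) of a filtered sample, per volume filtered:
#' `(m1 - m2) / V`. Duplicate filter measurements are conventionally
#' averaged with `mean()` afterwards. (Note the subtraction order: VSS is
#' the volatile mass lost on ignition, so the dried mass m1 is the larger.)
#'
#' @param mass_dried Filter mass after drying (g), vectorised.
#' @param mass_ashed Filter mass after ignition (g).
#' @param volume_filtered Sample volume filtered (L), > 0.
#' @return VSS concentration(s) in g/L.
#' @examples
#' vss_concentration(0.1050, 0.1020, 0.010) # 0.30 g/L
#' @export
vss_concentration <- function(mass_dried, mass_ashed, volume_filtered) {
  if (any(volume_filtered <= 0)) ck_abort("`volume_filtered` must be > 0", "validation")
  if (any(mass_ashed < 0)) ck_abort("masses must be >= 0", "validation")
  if (any(mass_ashed > mass_dried)) {
    ck_abort("ashed mass exceeds dried mass; check the measurement", "validation")
  }
  (mass_dried - mass_ashed) / volume_filtered
}

#' Biomass yield on glucose
#'
#' `Y_X/S = (VSS_final - VSS_inoculum) / (glucose_initial - glucose_final)`
#' in g biomass per g glucose. The inoculum's VSS contribution is
#' subtracted so the yield reflects growth during the experiment. A
#' negative numerator (final biomass below the inoculum contribution) is
#' allowed but warned about.
#'
#' @param glucose_initial,glucose_final Glucose concentrations (g/L),
#'   initial >= final >= 0.
#' @param vss_final Final biomass concentration (g VSS/L).
#' @param vss_inoculum VSS added by the inoculum (g/L).
#' @return Yield in g biomass / g glucose.
#' @export
biomass_yield <- function(glucose_initial, glucose_final, vss_final,
                          vss_inoculum = 0) {
  if (glucose_final < 0 || glucose_initial < glucose_final) {
    ck_abort("need glucose_initial >= glucose_final >= 0", "validation")
  }
  consumed <- glucose_initial - glucose_final
  if (consumed == 0) ck_abort("no glucose consumed; yield undefined", "validation")
  dx <- vss_final - vss_inoculum
  if (dx < 0) ck_warn("final VSS below the inoculum contribution: negative yield", "balance")
  dx / consumed
}

#' Electron equivalents per mole from an elemental formula
#'
#' Degree-of-reduction convention: `4 C + H - 2 O - 3 N` electrons
#' available per mole on full oxidation to CO2, H2O and NH3. Glucose
#' gives 24, caproate 32, H2 gives 2, CO2 gives 0; the standard biomass
#' composition CH1.8O0.5N0.2 gives 4.2 per C-mol.
#'
#' @param formula Named numeric vector/list with (a subset of) C, H, O, N
#'   counts, all >= 0 and not all zero.
#' @return Electron moles per mole of compound.
#' @examples
#' electrons_per_mol(c(C = 6, H = 12, O = 6)) # glucose: 24
#' @export
electrons_per_mol <- function(formula) {
  f <- c(C = 0, H = 0, O = 0, N = 0)
  formula <- unlist(formula)
  bad <- setdiff(names(formula), names(f))
  if (length(bad)) {
    ck_abort(paste0("unsupported element(s): ", paste(bad, collapse = ", ")),
             "contract")
  }
  f[names(formula)] <- formula
  if (any(f < 0)) ck_abort("element counts must be >= 0", "contract")
  if (all(f == 0)) ck_abort("formula has no atoms", "contract")
  unname(4 * f["C"] + f["H"] - 2 * f["O"] - 3 * f["N"])
}

#' Degree-of-reduction electron balance over a fermentation
#'
#' Converts each compound's concentration change to electron
#' milliequivalents (mmol e-/L = |delta g/L| / molar mass * 1000 *
#' electrons per mol) and compares electrons recovered in products,
#' biomass and gases against electrons consumed from substrates. A
#' recovery fraction near 1 means all fermentation products were
#' measured; a recovery outside [0.9, 1.1] triggers a warning flag.
#' A gCOD view is included (8 g COD per e-mol).
#'
#' @param entries Tibble/data frame with columns `compound` (registry
#'   name), `delta_g_l` (consumed negative, produced positive) and `role`
#'   (one of substrate, product, biomass, gas). Zero-delta buffer
#'   compounds simply contribute nothing.
#' @param registry A [compound_registry()].
#' @return Object of class `electron_balance`: per-entry `table` (with
#'   `emeq` in mmol e-/L and `gCOD` in g/L), `consumed`, `recovered`,
#'   `recovery_fraction`, `balanced` flag.
#' @export
electron_balance <- function(entries, registry = compound_registry()) {
  roles <- c("substrate", "product", "biomass", "gas")
  if (!all(entries$role %in% roles)) {
    ck_abort(paste0("roles must be one of: ", paste(roles, collapse = ", ")),
             "contract")
  }
  if (!any(entries$role == "substrate")) {
    ck_abort("an electron balance needs at least one substrate entry", "contract")
  }
  tab <- entries
  tab$molar_mass <- vapply(tab$compound, function(nm)
    find_compound(nm, registry)$molar_mass, numeric(1), USE.NAMES = FALSE)
  tab$e_per_mol <- vapply(tab$compound, function(nm)
    find_compound(nm, registry)$electrons_per_mol, numeric(1),
    USE.NAMES = FALSE)
  tab$mmol_l <- abs(tab$delta_g_l) / tab$molar_mass * 1000
  tab$emeq <- tab$mmol_l * tab$e_per_mol
  tab$gCOD <- tab$emeq * 8 / 1000
  consumed <- sum(tab$emeq[tab$role == "substrate"])
  recovered <- sum(tab$emeq[tab$role != "substrate"])
  if (consumed == 0) ck_abort("substrate electron consumption is zero", "contract")
  recovery <- recovered / consumed
  structure(
    list(table = tibble::as_tibble(tab), consumed = consumed,
         recovered = recovered, recovery_fraction = recovery,
         balanced = recovery >= 0.9 && recovery <= 1.1),
    class = "electron_balance"
  )
}

#' @export
print.electron_balance <- function(x, ...) {
  cat(sprintf("<electron_balance> recovery %.3f (%.1f of %.1f mmol e-/L)%s\n",
              x$recovery_fraction, x$recovered, x$consumed,
              if (x$balanced) "" else "  [OPEN: outside 0.9-1.1]"))
  print(x$table[, c("compound", "role", "delta_g_l", "emeq", "gCOD")])
  invisible(x)
}
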