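# Weak-acid speciation (total vs undissociated forms across pH) and
# g/L <-> mM unit conversions, driven by a YAML compound registry.

#' Load the compound registry
#'
#' The registry ships as `extdata/compounds.yaml` (name, synonyms,
#' elemental C/H/O/N formula, molar mass, pKa for weak acids) and can be
#' overridden with a user file of the same layout. Each entry's molar
#' mass is checked against its formula (within 0.1%); for acids the pKa
#' must lie in (0, 14).
#'
#' @param path Optional path to a YAML registry; default is the shipped one.
#' @return A list of compound entries (class `compound_registry`), each
#'   with `name`, `synonyms`, `formula` (named C/H/O/N vector),
#'   `molar_mass`, `pKa` (NA for non-acids) and `electrons_per_mol`.
#' @export
compound_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compounds.yaml", package = "caprokin")
  }
  raw <- yaml::read_yaml(path)
  entries <- lapply(raw$compounds, function(cc) {
    f <- c(C = 0, H = 0, O = 0, N = 0)
    f[names(cc$formula)] <- unlist(cc$formula)
    mm_formula <- sum(f * c(C = 12.011, H = 1.008, O = 15.999, N = 14.007))
    if (abs(cc$molar_mass - mm_formula) / mm_formula > 0.001) {
      ck_abort(sprintf(
        "registry entry '%s': molar mass %.4g inconsistent with formula (%.4g)",
        cc$name, cc$molar_mass, mm_formula), "registry")
    }
    pka <- if (is.null(cc$pKa)) NA_real_ else as.numeric(cc$pKa)
    if (!is.na(pka) && (pka <= 0 || pka >= 14)) {
      ck_abort(sprintf("registry entry '%s': pKa %.3g outside (0, 14)",
                       cc$name, pka), "registry")
    }
    list(name = cc$name,
         synonyms = as.character(unlist(cc$synonyms %||% character())),
         formula = f, molar_mass = as.numeric(cc$molar_mass), pKa = pka,
         electrons_per_mol = electrons_per_mol(f))
  })
  names(entries) <- vapply(entries, `[[`, character(1), "name")
  structure(entries, class = "compound_registry")
}

#' Look up a compound by name or synonym
#'
#' @param name Compound name (case-insensitive; synonyms accepted).
#' @param registry A [compound_registry()].
#' @return The registry entry (list).
#' @export
find_compound <- function(name, registry = compound_registry()) {
  key <- tolower(trimws(name))
  for (cc in registry) {
    if (key == tolower(cc$name) || key %in% tolower(cc$synonyms)) return(cc)
  }
  ck_abort(sprintf("compound '%s' not found in the registry", name), "registry")
}

#' Fraction of a weak acid in the undissociated (protonated) form
#'
#' Henderson–Hasselbalch: `1 / (1 + 10^(pH - pKa))`. The undissociated
#' form is the uncharged, membrane-permeant species that drives toxicity;
#' its fraction decreases with pH and increases with pKa.
#'
#' @param pH,pKa Finite numbers (vectors recycle).
#' @return Fraction in (0, 1).
#' @examples
#' undissociated_fraction(5.5, 4.88)
#' @export
undissociated_fraction <- function(pH, pKa) {
  if (any(!is.finite(pH)) || any(!is.finite(pKa))) {
    ck_abort("`pH` and `pKa` must be finite", "contract")
  }
  1 / (1 + 10^(pH - pKa))
}

#' Convert a concentration from g/L to mM (and back)
#'
#' `mM = g/L * 1000 / molar_mass`; [mM_to_gl()] is the exact inverse.
#'
#' @param conc Concentration (>= 0).
#' @param compound Registry name or synonym.
#' @param registry A [compound_registry()].
#' @export
gl_to_mM <- function(conc, compound, registry = compound_registry()) {
  if (any(conc < 0)) ck_abort("concentration must be >= 0", "contract")
  conc * 1000 / find_compound(compound, registry)$molar_mass
}

#' @rdname gl_to_mM
#' @export
mM_to_gl <- function(conc, compound, registry = compound_registry()) {
  if (any(conc < 0)) ck_abort("concentration must be >= 0", "contract")
  conc * find_compound(compound, registry)$molar_mass / 1000
}

#' Speciate a weak acid at a given pH
#'
#' Splits a total acid concentration into its undissociated (protonated)
#' part at the given pH and reports both in g/L and mM.
#'
#' @param total Total acid concentration, >= 0.
#' @param unit Unit of `total`: `"g_l"` or `"mM"`.
#' @param pH Medium pH.
#' @param compound Registry name of a weak acid (must have a pKa).
#' @param registry A [compound_registry()].
#' @return Object of class `acid_speciation`: `compound`, `pH`, `pKa`,
#'   `total_g_l`, `total_mM`, `undissociated_g_l`, `undissociated_mM`,
#'   `fraction_undissociated`.
#' @examples
#' speciate(13.6, "g_l", pH = 5.5, compound = "caproate")
#' @export
speciate <- function(total, unit = c("g_l", "mM"), pH,
                     compound = "caproate", registry = compound_registry()) {
  unit <- match.arg(unit)
  if (!is_number(total) || total < 0) ck_abort("`total` must be >= 0", "contract")
  cmp <- find_compound(compound, registry)
  if (is.na(cmp$pKa)) {
    ck_abort(sprintf("compound '%s' has no pKa; speciation undefined", cmp$name),
             "contract")
  }
  total_g_l <- if (unit == "g_l") total else mM_to_gl(total, cmp$name, registry)
  total_mM <- if (unit == "mM") total else gl_to_mM(total, cmp$name, registry)
  f <- undissociated_fraction(pH, cmp$pKa)
  structure(
    list(compound = cmp$name, pH = pH, pKa = cmp$pKa,
         total_g_l = total_g_l, total_mM = total_mM,
         undissociated_g_l = f * total_g_l, undissociated_mM = f * total_mM,
         fraction_undissociated = f),
    class = "acid_speciation"
  )
}

#' @export
print.acid_speciation <- function(x, ...) {
  cat(sprintf("<acid_speciation> %s at pH %.2f (pKa %.2f)\n",
              x$compound, x$pH, x$pKa))
  cat(sprintf("  total:         %.4g g/L = %.4g mM\n", x$total_g_l, x$total_mM))
  cat(sprintf("  undissociated: %.4g g/L = %.4g mM (fraction %.4f)\n",
              x$undissociated_g_l, x$undissociated_mM, x$fraction_undissociated))
  invisible(x)
}
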