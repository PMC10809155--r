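---
title: "Growth kinetics, caproate inhibition and electron balances with caprokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth kinetics, caproate inhibition and electron balances with caprokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprokin)
```

## The problem

Sugar-fed chain-elongation bioprocesses produce caproic acid through a
community dominated by two guilds: lactic acid bacteria (LAB), which ferment
glucose to lactate, and chain-elongating bacteria (CEB), which elongate
short-chain acids to caproate by reverse β-oxidation. Understanding why LAB
persist in these systems comes down to a handful of kinetic quantities per
organism: the maximum specific growth rate μ~m~, the lag time λ, the glucose
half-saturation constant K~S~, the biomass yield Y~X/S~, and the caproic acid
concentration at which growth stops. caprokin implements the full inference
chain from raw growth-signal time series to those quantities, with bootstrap
uncertainty, and adds the weak-acid speciation and electron-balance
arithmetic needed to interpret them.

## Primary model: modified Gompertz

Each replicate curve is normalised to its initial signal and fitted with the
Zwietering parameterisation of the Gompertz equation,

$$y(t) = A\,\exp\!\Big(-\exp\big(\tfrac{\mu_m e}{A}(\lambda - t) + 1\big)\Big),$$

whose parameters are directly interpretable: $A$ is the asymptotic
normalised growth, $\mu_m$ the maximal slope of $y(t)$ (h⁻¹), and $\lambda$
the lag time (h). Two normalisation modes exist. The default is
`log` ($y = \ln(\mathrm{signal}/\mathrm{signal}_0)$), under which $\mu_m$ is a
specific growth rate in h⁻¹ — the unit in which growth rates of LAB and CEB
are conventionally reported. `linear` mode ($y = \mathrm{signal}/\mathrm{signal}_0$,
fitted on $y-1$) is retained because some instruments and conventions work
on the plain OD ratio; under it $\mu_m$ is a signal-ratio rate, not a
specific growth rate.

One consequence of normalising by the *first measured* signal is a small
systematic offset: the Gompertz curve has $y(\lambda\!=\!0\text{ point}) > 0$,
so an observed curve forced through $y(0)=0$ sits about
$A e^{-\exp(\mu_m e \lambda / A + 1)}$ below the model at $t = 0$
(≈ 0.005 log units for typical parameters here). This is a property of the
experiment itself, not of the fit; it biases recovered parameters by well
under 1% at the noise levels considered and is ignored.

Parameters are estimated by minimising the root-mean-squared deviation

$$\mathrm{RMSD} = \sqrt{\tfrac1m \sum_{i=1}^m (\hat y_i - y_i)^2}$$

with a deterministic multi-start strategy: data-driven initial values
($A_0 = \max y$; $\mu_0$ = steepest finite-difference slope; $\lambda_0$ =
intercept of the max-slope tangent with $y = 0$), each perturbed ±50% to a
3×3×3 start grid, each start refined by bounded quasi-Newton minimisation
(`nlminb`), best result kept, exact ties broken by the lexicographically
smallest parameter vector. Bounds are $A \in (0, 2\max y]$,
$\mu_m \in (0, 10\mu_0]$, $\lambda \in [0, \max t]$. Curves whose normalised
signal never rises above the growth threshold (default 0.05 log units,
≈ 5% signal increase) are flagged `no_growth` rather than fitted; the
threshold is configurable in `fit_config()`.

## Secondary models

Condition-level rates (the mean of replicate $\mu_m$) feed two secondary
models, mirroring the two-stage practice of fitting curves first and rates
second rather than jointly refitting all raw curves:

* **Monod affinity** — $\mu = \mu_{max} S/(K_S + S)$ fitted to (glucose,
  rate) points spanning concentrations below and above $K_S$.
* **Linear product inhibition** — $\mu = \mu_{max}(1 - K P)$ fitted to
  (caproate, rate) points, with the growth-inhibitory concentration
  extrapolated as $P_{inhib} = 1/K$. Rates are first normalised by the mean
  rate of the 0 g/L replicates (`normalize_rates()`), so $\mu_{max}$ is
  dimensionless and close to 1. Conditions where growth never occurred are
  *excluded* by default: the model describes the decline of measured rates
  and is extrapolated to zero, and including hard zeros from beyond the
  threshold would flatten the line and bias $K$ downward
  (`include_zero_rates = TRUE` restores them). The clamp at zero applies to
  prediction only; the fit uses the unclamped line.

A Welch unequal-variances *t*-test screens each concentration against the
0 g/L baseline (`screen_inhibition_significance()`). No multiple-testing
correction is applied by default, matching the pairwise-reporting
convention for such dose screens; `adjust = "holm"` is available.

## Uncertainty: bootstrap and Monte Carlo

`bootstrap_parameters()` refits the model on resampled data, with the
scheme chosen by data shape:

* *residual resampling* for time-series (Gompertz) fits — resample the base
  fit's residuals and refit on fitted + resampled residuals, preserving the
  time design;
* *case resampling stratified by concentration* for rate-table fits — every
  concentration level keeps its replicate count, so the design is never
  degenerate in a resample.

These are the standard choices for each data shape; the refits start from
the base point estimate, which is both conventional and fast. Derived
quantities such as $P_{inhib} = 1/K$ get their uncertainty from
`propagate_uncertainty()`: Monte-Carlo resampling of bootstrap parameter
vectors, evaluating the derived function on each draw (non-positive $K$
draws yield no finite threshold and are dropped and counted), and
summarising mean, sd and percentile interval. Defaults: `n_boot = 1000`,
`n_mc = 10000`, 95% percentile intervals, mandatory seed (default 1291007)
so every report is exactly reproducible.

## Weak-acid speciation

Toxicity of caproic acid is driven by its undissociated (protonated,
membrane-permeant) form, whose fraction at a given pH follows
Henderson–Hasselbalch: $f = 1/(1 + 10^{\mathrm{pH} - \mathrm{p}K_a})$.
`speciate()` splits a total concentration into the undissociated part and
reports both in g/L and mM. The shipped registry uses pK~a~ = 4.88 and
116.16 g/mol for caproic acid; the pK~a~ was back-calculated as the unique
value consistent with the package's reference total→protonated pairs at
pH 5.5 and agrees with literature values for hexanoic acid (≈ 4.85–4.88).
Temperature dependence of pK~a~ and activity corrections are ignored —
concentrations are treated as activities, consistent with the desk
arithmetic the module reproduces. Polyprotic acids are out of scope.

## Electron balances and yields

`electron_balance()` keeps a degree-of-reduction ledger: each compound's
concentration change is converted to electron milliequivalents
(mmol e⁻/L) using $4C + H - 2O - 3N$ electrons per mole, and recovery is
electrons in products, biomass and gases over electrons from substrates.
CO₂ carries zero electrons, so a closed balance (recovery ≈ 1) means all
reduced products were measured; the report flags recoveries outside
[0.9, 1.1]. A gCOD view (8 g COD per e⁻-mol) is included. Biomass uses the
standard cell composition CH₁.₈O₀.₅N₀.₂ (4.2 e⁻ per C-mol, 24.63 g/C-mol),
overridable through the registry. VSS follows Standard Methods 2540E as
$(m_1 - m_2)/V$ — the volatile mass lost between drying and ignition; note
that the dried mass $m_1$ is necessarily the larger, and the implementation
enforces this. Yields are $Y_{X/S} = \Delta X / \Delta S$ with the
inoculum's VSS contribution subtracted from $\Delta X$.

## What the synthetic data emulate — and what they do not

No raw growth curves are distributed with instruments like plate-imaging
microscopes; `simulate_*` generators therefore emulate the reference
experimental designs so the whole pipeline is testable:

* `serum_bottle_growth` — triplicate bottles, Gompertz truth
  (A = 1.5 log units, μ~m~ = 0.051 h⁻¹, λ = 8 h), 61 samples over 120 h;
* `ks_high_tryptone` — quadruplicate glucose gradient
  {0, 0.05, 0.1, 0.25, 0.5, 1, 2, 4, 6} g/L, Monod truth
  μ~max~ = 0.06 h⁻¹, K~S~ = 0.35 g/L;
* `inhibition_lm` / `inhibition_lr` — quadruplicate caproate gradients
  (0–12 g/L in the two plate layouts), linear truths 1/K = 13.6 and
  8.9 g/L; levels beyond 1/K yield no-growth wells.

The noise model is additive Gaussian on log-normalised signal
(equivalently multiplicative on the raw signal, matching the roughly
multiplicative error of backscatter/absorption instruments; default
σ = 0.02 log units, a calibration choice — the instruments' true noise
magnitude is not published) and relative Gaussian on rate tables (default
5%). A single master seed drives all replicates, and generators restore
the caller's RNG state. What the generators do **not** emulate: instrument
drift and well-position effects, biological replicate-to-replicate
parameter variation (noise is around a common truth), substrate depletion
feeding back on the curve shape, and plate-edge artefacts. Passing
recovery tests on these data therefore demonstrates correctness of the
inference machinery under the stated error model, not robustness to every
failure mode of real plates.

## Validation studies and problem sizes

The test suite validates the pipeline by generate-then-fit: noiseless
datasets must return their generating parameters to 10⁻⁴ relative or
better; the optimizer must never lose to a 30³ brute-force grid over its
own bounds (20 random instances); noisy quadruplicate designs over 100
seeds must recover μ~m~ within 5%, K~S~ within 20% (≥ 90% of seeds) and
P~inhib~ within 5% of truth at the default noise; bootstrap 95% intervals
for μ~m~ must cover the truth in at least 88% of 200 synthetic datasets
(40-point curves, 200 bootstrap refits each — sizes chosen to keep the
full study comfortably under two minutes while leaving Monte-Carlo error
on the coverage estimate near 2%); and the Welch screen's type-I error
under the null must sit near 5% over 1000 simulated plates. Balanced
stoichiometries (including 1.5 glucose → 1 caproate + 3 CO₂ + 2 H₂ +
1 H₂O) must close the electron ledger to 10⁻⁶.

## Worked example

```{r, eval = FALSE}
library(caprokin)

# simulate the tolerant-strain inhibition plate and re-infer the threshold
d <- design_fixture("inhibition_lm")
rates <- simulate_inhibition_experiment(d, seed = 1)
fit <- fit_inhibition(normalize_rates(rates, baseline_x = 0),
                      fit_config(n_boot = 1000, seed = 1))
fit
speciate(fit$P_inhib, "g_l", pH = 5.5, compound = "caproate")
```

## Known limitations

* Only the Gompertz primary model and the Monod / linear-inhibition
  secondary models are implemented; Baranyi, logistic and curved
  (e.g. Han–Levenspiel) inhibition alternatives are out of scope.
* The lag time λ is reported but not modelled as a function of inhibitor
  concentration (the generator can inflate it linearly for testing).
* Uncertainty is frequentist bootstrap only — no analytic (Hessian)
  standard errors, no Bayesian posterior.
* Speciation assumes a single pK~a~ and ideal solutions.
* Whether plate-imaging total-absorption values and backscatter signals
  share a scale is unknown; each experiment's signals are treated as
  internally consistent only, which normalisation to the initial value
  makes sufficient.
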