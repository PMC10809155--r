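# caprokin

Growth-kinetics inference for chain-elongation microbiomes: modified
Gompertz fitting of replicated growth curves, Monod substrate affinity,
linear caproic-acid inhibition with extrapolated inhibitory
concentrations, bootstrap/Monte-Carlo uncertainty, weak-acid speciation,
and degree-of-reduction electron balances.

## Who this is for

Caproic acid (hexanoate) is produced from sugars by open-culture
bioprocesses in which lactic acid bacteria (LAB) and chain-elongating
bacteria (CEB) coexist. Steering such communities requires the kinetic
fingerprints of their members — maximum specific growth rate μ<sub>m</sub>,
lag time λ, glucose half-saturation constant K<sub>S</sub>, biomass yield
Y<sub>X/S</sub>, and the caproate concentration at which growth stops.
caprokin turns plate-reader or serum-bottle growth signals into those
quantities with honest uncertainty, and provides the speciation and
electron-balance bookkeeping needed to interpret them.

## The models

Each normalised curve y(t) = ln(signal/signal₀) is fitted with the
Zwietering-form Gompertz model

    y(t) = A · exp(−exp(μₘ·e/A · (λ − t) + 1))

by deterministic multi-start RMSD minimisation. Condition-level rates then
feed a secondary model:

* Monod: μ = μ_max · S / (K_S + S)
* linear inhibition: μ = μ_max · (1 − K·P), with the growth-inhibitory
  concentration extrapolated as P_inhib = 1/K

Parameter uncertainty comes from bootstrap resampling (residuals for
curves, stratified cases for rate tables) and Monte-Carlo propagation for
derived quantities such as 1/K. Weak-acid speciation uses
Henderson–Hasselbalch (fraction undissociated = 1/(1+10^(pH−pKa)));
electron balances use the degree-of-reduction convention
(4C + H − 2O − 3N electrons per mole).

## Worked example

Simulate the quadruplicate caproate-inhibition plate of a tolerant strain
(levels 0–12 g/L, truth P_inhib = 13.6 g/L), re-infer the threshold with
bootstrap uncertainty, and speciate it at the culture pH:

```r
library(caprokin)

d <- design_fixture("inhibition_lm")
rates <- simulate_inhibition_experiment(d, seed = 1)
fit <- fit_inhibition(normalize_rates(rates, baseline_x = 0),
                      fit_config(n_boot = 1000, seed = 1))
fit
#> <inhibition_fit> mu_max = 1.005, K = 0.0737 L/g (rmsd 0.0248, n 40)
#>   P_inhib = 13.6 +/- 0.085 g/L (117 +/- 0.73 mM)

speciate(fit$P_inhib, "g_l", pH = 5.5, compound = "caproate")
#> <acid_speciation> caproate at pH 5.50 (pKa 4.88)
#>   total:         13.57 g/L = 116.8 mM
#>   undissociated: 2.625 g/L = 22.6 mM (fraction 0.1935)
```

The fit recovers the generating threshold (13.6 g/L ≈ 117 mM total
caproate) and reports that at pH 5.5 about 19.3% of it — 22.6 mM — is in
the undissociated, membrane-permeant form that drives toxicity. A Welch
screen against the 0 g/L baseline (`screen_inhibition_significance(rates, 0)`)
shows the rate decrease is significant from 2 g/L upward on this dataset.

The full pipeline (read CSV curves → Gompertz fits → condition summary →
secondary fit → speciation → CSV/JSON reports) runs from one config:
`run_growth_pipeline(pipeline_config("config.yaml"))`. See the vignette
(`vignettes/growth-kinetics.Rmd`) for models, assumptions, defaults and
validation details.

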