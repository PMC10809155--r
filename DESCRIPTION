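Package: caprokin
Title: Growth Kinetics, Product Inhibition and Electron Balances for
    Chain-Elongation Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infrastructure for characterising microbial growth in
    sugar-based chain-elongation communities. Fits the modified Gompertz
    model to replicated growth-signal time series to extract maximum
    specific growth rates, lag times and growth asymptotes; fits Monod
    substrate-affinity and linear product-inhibition models to
    condition-level rates, extrapolating the growth-inhibitory caproic
    acid concentration; quantifies uncertainty by bootstrap resampling
    and Monte-Carlo propagation; performs weak-acid (caproate)
    speciation between total and undissociated forms across pH; and
    keeps degree-of-reduction electron balances and biomass-yield
    bookkeeping over fermentation products. Ships a synthetic-data
    generator emulating 96-well and serum-bottle growth experiments so
    that the whole pipeline can be exercised and validated without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
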