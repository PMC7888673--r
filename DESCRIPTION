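Package: swapsim
Title: Simulation and Analysis of Lower-Energy Food-Swap Trials in Online
    Supermarkets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying checkout "swap" interventions in simulated
    online supermarkets: a rule-based algorithm that finds lower-energy
    alternatives to basket items (same shelf category, 90-110% of the
    weight, cheaper by at most 20%, at least 100 kJ/100 g less energy
    dense), a synthetic shopper cohort with a logistic frame- and
    age-dependent acceptance process, permuted-block randomisation with an
    exclusion ledger, the pre-registered analysis plan (clustered logistic
    acceptance models with fixed-effect fallback, multilevel energy-change
    models, paired basket and nutrient tests, Bonferroni families), and a
    simulation-based power calculator with a closed-form oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
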