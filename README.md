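# swapsim

Simulation and analysis of lower-energy food-swap trials in online
supermarkets.

When an online supermarket detects an energy-dense product in a shopper's
basket at checkout, it can offer a "swap": one or two alternatives from the
same shelf that weigh about the same (90–110%), cost less (by at most 20%),
and are less energy dense by at least 100 kJ (23.9 kcal) per 100 g.
`swapsim` is a research compendium for the three-arm randomised design that
tests whether framing such swaps as a *health* benefit, a *cost* saving, or
a *social norm* changes acceptance. It is aimed at behavioural-nutrition and
trial-methodology researchers who want to study, power, or reanalyse this
class of intervention without access to a live shopping platform.

The package provides, as separately usable modules:

* **catalog** — product/basket data model, kcal and nutrient accounting,
  CSV I/O (`catalog()`, `read_catalog()`, `basket_totals()`);
* **swap engine** — the four-criteria eligibility filter and checkout offer
  construction (`swap_criteria()`, `is_eligible()`,
  `eligible_alternatives()`, `offer_swaps_at_checkout()`,
  `apply_decision()`);
* **synthetic cohort** — generators for catalogs with guaranteed swap
  structure, shopper demographics matching the trial's baseline table,
  12-item shopping with configurable noise, and a logistic acceptance
  process with participant random intercepts (`generate_catalog()`,
  `generate_participants()`, `simulate_shopping()`,
  `acceptance_probability()`);
* **trial** — permuted-block randomisation, the five exclusion rules with a
  first-hit ledger, end-to-end orchestration, and a fixture rebuilt from
  the trial's printed counts (`run_trial()`, `apply_exclusions()`,
  `build_paper_counts_fixture()`);
* **analysis** — the pre-registered plan: descriptives, logistic acceptance
  models with a flagged fixed-effect fallback, multilevel per-swap
  energy-change models, paired basket/nutrient t-tests, frame regressions,
  balance checks, Bonferroni families (`descriptives()`,
  `fit_acceptance_model()`, `fit_energy_change_model()`,
  `basket_change_tests()`, `bonferroni_alpha()`);
* **power** — a simulation-based power calculator for the clustered,
  SES-moderated two-proportion design, with a closed-form oracle
  (`power_design()`, `estimate_power()`, `analytic_power_two_prop()`,
  `required_n()`).

The acceptance model at the core of both the generator and the analysis is,
on the log-odds scale,

```
logit P(accept) = b0 + b_frame + b_age (age − 47) + b_income×frame + u_i ,
u_i ~ N(0, sigma^2)
```

with `b0 = logit(0.13)` (the headline acceptance rate), `b_age = 0.02` per
year, null frame and interaction effects by default, and a participant
random intercept `u_i` (sd 0.5). Energy-change outcomes are analysed with a
time-dummy multilevel linear model per offer and paired t-tests per basket;
families of related tests use Bonferroni thresholds .025 (two primary
models, two energy models) and .017 (three basket tests, three nutrient
tests).

## Worked example

```r
library(swapsim)

td <- run_trial(seed = 42)   # 900 shoppers, default study conditions
td
#> <trial_data> 900 participants (730 included), 2665 swap offers, 730 basket rows

summary(td)
#> Swap offers: 2368, accepted 316 (13.34%)
#> Participants: 730, accepting >=1 swap: 242 (33.2%)
#> Offers per participant: M = 3.24, SD = 1.43
#>          arm offers accepted acceptance_pct participants accepting_participants
#>       health    817      106          12.97          253                     82
#>         cost    772      110          14.25          232                     81
#>  social_norm    779      100          12.84          245                     79
#> ...
#> Per offer: observed -6.45 kcal, potential -48.75 kcal
#> Per basket: observed reduction 20.92 kcal, potential reduction 158.15 kcal

fit_acceptance_model(td)     # primary unadjusted model, family alpha .025
#> <swap_fit> acceptance (unadjusted) (family alpha = 0.025)
#>                      term estimate   se statistic        p
#>               (Intercept)    -1.47 0.30     -4.97 6.53e-07
#>            n_alternatives    -0.30 0.13     -2.24 2.49e-02
#>  n_offers_for_participant     0.02 0.04      0.51 6.08e-01
#>                 framecost     0.11 0.15      0.73 4.65e-01
#>          framesocial_norm    -0.01 0.15     -0.04 9.68e-01
```

Reading the output: ~13% of checkout offers are accepted (the configured
headline rate); the frame coefficients are null by design, and their Wald
tests are judged against the family-adjusted threshold of .025. The
observed per-basket reduction is the product of the acceptance rate and the
per-offer energy gap; the "potential" rows show the counterfactual in which
every offer is accepted.

The 730-of-900 inclusion rate reflects the five exclusion rules at their
observed frequencies (short baskets, off-list shopping, BMI below 18,
missing demographics, no swap-eligible items); `td$exclusions` holds the
per-reason ledger.

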