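---
title: "Simulating and analysing lower-energy swap trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing lower-energy swap trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swapsim)
```

## The problem

Online supermarkets can suggest a lower-energy "swap" when a shopper
reaches the checkout with an energy-dense product in their basket. In the
randomised experiment this package emulates, shoppers in a simulated store
bought a 12-item list on a £25 budget, and at checkout each swap-relevant
item triggered an offer showing one or two cheaper, lighter alternatives,
framed either as a health benefit, a cost saving, or a social norm.
`swapsim` re-implements the whole computational machinery of such a trial —
the substitution algorithm, a synthetic shopper cohort, the randomised
trial itself, the pre-registered analysis plan, and a simulation-based
power calculator — so the design and analysis can be exercised end to end
without access to the original platform or raw data.

## The swap-eligibility algorithm

A candidate is an eligible alternative for an original choice when all
four criteria hold:

1. same shelf category (the retailer's shelf location taxonomy);
2. pack weight between 90% and 110% of the original (both bounds
   inclusive);
3. strictly cheaper, but by at most 20% (lower bound inclusive — the rule
   is "costs less, by a maximum of 20%", with no minimum difference);
4. energy density lower by at least 100 kJ (= 100/4.184 = 23.9006 kcal)
   per 100 g (inclusive).

Where the wording of the protocol leaves a boundary open, the most literal
reading is used and documented in `swap_criteria()`. Two numerical
choices deserve emphasis:

* the density threshold defaults to the *exact* conversion 23.9006
  kcal/100 g rather than the rounded 24, because the kJ figure is the
  primary definition; both are configurable;
* when more than two candidates qualify, the protocol does not state a
  selection rule. The package ranks by descending density reduction, then
  ascending price, then product id — a deterministic, auditable convention
  — and shows the top two. The "potential" (all-swaps-accepted) energy
  change uses the top-ranked alternative as comparator, again a declared
  convention.

Offers happen once, at checkout, for every swap-relevant basket item;
accepting an offer never re-triggers evaluation of other items or of the
swapped-in product.

```{r}
cat <- generate_catalog(cohort_config(), seed = 1)
head(eligible_alternatives(cat$products$product_id[1], cat)[,
  c("product_id", "price_gbp", "pack_weight_g", "energy_kcal_per_100g")])
```

## What the synthetic generator emulates

The generator's defaults encode the trial's study conditions, so a default
`run_trial()` is a faithful in-silico replica of the design:

* **Cohort** (`generate_participants()`): 900 shoppers; age a truncated
  normal on 18–97 recentred so the post-truncation mean is 47.7 (SD 15.9);
  52% female; BMI truncated-normal 27.2 (6.3) on 18–40; education and
  income drawn from the trial's baseline marginals; 2.4% of shoppers
  report BMI below 18, and 0.33% lack income data, feeding the exclusion
  rules.
* **Catalog** (`generate_catalog()`): 20 shelf categories of 15 products.
  A quarter-ish of products (`eligible_share` = 0.26, realised as 4/15)
  are high-density "targets" paired by construction with one or two
  eligible partners in the same pack-weight band: 5% lighter to 5%
  heavier, 2–18% cheaper, 30–50 kcal/100 g less dense. Distinct weight
  bands are separated by a factor 1.25, which keeps them outside each
  other's 90–110% window, so the share of products with an eligible
  alternative is exact by construction, and eligibility never leaks
  between bands. Two-thirds of targets get two partners
  (`two_alt_share` = 0.67), matching the observed mix of one- and
  two-alternative offers.
* **Shopping** (`simulate_shopping()`): a 12-slot list (9 targeted
  categories, 3 open-ended slots) with one uniformly chosen product per
  listed category. With probability 0.126 a shopper checks out with only
  4–9 items, and with probability 0.022 they replace 3–5 items with
  off-list products — the observed rates of exclusion rules (i) and (ii).
  With 4/15 of products swap-relevant, a 12-item basket yields about 3.2
  offers on average, matching the observed 3.17.
* **Acceptance** (`acceptance_probability()`): a logistic model — the
  model the pre-registered analysis assumes — with intercept
  `qlogis(0.13)` (the headline ~13% acceptance rate; no intercept is
  published, so this is a calibration, not a reported coefficient), frame
  offsets of zero (the trial's null result), an age slope of 0.02 per year
  centred at age 47 so the intercept is the acceptance rate of an
  average-age shopper, a zero income-by-frame interaction, and a
  participant random intercept with SD 0.5 — a mild within-shopper
  correlation (ICC about 0.07 on the latent scale). The random-effects
  structure is deliberately the one the original analysis *planned*; the
  fitted model's fixed-effect fallback (below) then reproduces the
  documented analysis path.

**Seed discipline.** One master seed drives everything. Draws tied to a
participant (shopping, random intercepts) come from substreams keyed by a
stable hash of the participant id (`substream_seed()`), so editing one
part of a cohort does not reshuffle every other shopper's draws. The same
`(config, seed)` pair reproduces every table byte for byte.

What the generator does **not** emulate: taste, brand loyalty, price
sensitivity or any behavioural theory of choice; item quantities (one unit
per slot); and the questionnaire instruments (attention and responsibility
screeners appear only as pass flags). Passing tests therefore demonstrate
that the pipeline's *statistical* structure is correct, not that real
shoppers behave like the generator.

## The trial and its exclusion ledger

`run_trial()` randomises 1:1:1 with permuted blocks — a deliberate
divergence from the platform randomisation of the original trial (which
produced slightly unequal arms), because exact arm sizes make simulation
tests sharper. The five exclusion rules are applied in their published
order with first-hit attribution: fewer than 10 products; more than two
off-list products; BMI below 18; missing demographics; no swap-eligible
products. The precedence is not published; first-hit is the package's
reading, and the ledger (`$exclusions`) reports one primary reason per
excluded shopper. Two exact accounting identities hold on every simulated
dataset and are enforced by tests:

* final basket kcal = baseline kcal + sum of observed per-offer deltas;
* potential basket kcal = baseline kcal + sum of potential deltas.

## The analysis plan

`fit_acceptance_model()` fits the primary logistic models (unadjusted:
frame plus two controls — alternatives per offer, offers per shopper;
adjusted: plus age, gender, BMI, education, income, shopping
responsibility and frame-by-income), with reference levels health frame,
female, Bachelor's degree, income under £15,500. For the adjusted model a
participant-level random intercept is attempted first (`lme4`) with a
convergence check (optimizer code, convergence messages, singularity);
failure triggers an automatic, flagged fallback to the fixed-effect model
— the same fallback path the original analysis documented. The two primary
models form a Bonferroni family at 0.05/2 = .025.

`fit_energy_change_model()` casts each offer into a two-row long format
(time dummy 0/1) and regresses pack kcal on time with a participant random
intercept (Satterthwaite degrees of freedom via `lmerTest`), optionally
with frame-by-time moderation; because the design is balanced, the time
coefficient equals the mean per-offer change exactly. Basket-level change
uses paired t-tests (df = n − 1, two-sided) and OLS frame regressions;
kcal and nutrient families use 0.05/3 = .017. `balance_checks()` runs the
chi-square/ANOVA randomisation checks. All p-values are two-sided.

Degenerate inputs fail loudly rather than silently: all-kept (or
all-accepted) outcomes, complete separation (named term), rank deficiency
(aliased terms listed), zero-variance paired differences, single-arm
balance tables. Toy inputs with constant covariates have those terms
dropped and recorded on the fit rather than producing NA rows.

## Power

`estimate_power()` makes the trial's design calculation reproducible as a
simulation with every assumption explicit: 25% baseline acceptance against
35% in a framed arm, ±12 percentage points of SES moderation between
extreme quartiles (implemented linear-in-logit and calibrated so the
extreme-quartile probability gap equals the configured offset), optional
repeated offers per shopper with a participant random intercept, and a
choice of participant-level proportion z-test or offer-level Wald test.
The closed form `analytic_power_two_prop()` — the unpooled
normal-approximation power — serves as an oracle in the uncorrelated
one-offer limit, where the simulator agrees with it to Monte-Carlo
precision (about 0.77 at 300 per arm). Because the original calculation's
method is unpublished, the published "900 shoppers for 80% power" figure
is treated as context, not as a target the simulator is tuned to.

```{r}
analytic_power_two_prop(0.25, 0.35, n_per_arm = 300)
```

## The printed-counts fixture

`build_paper_counts_fixture()` reconstructs the trial's offer, participant
and basket margins from its published counts, so the descriptive analysis
can be validated without any raw data. Two reconciliations were
unavoidable and are worth knowing about:

* the published per-arm offer and acceptance counts (741/740/812 and
  106/85/107) do not sum to the published totals (2262 and 292); the
  accepter counts do. The fixture follows the per-arm counts, so
  overall-level descriptives computed from it differ slightly from the
  published overall figures (13.00% vs 12.91% acceptance; 3.22 vs 3.17
  offers per shopper);
* the published basket-level potential reduction (494.97 kcal) and the
  per-offer potential reduction (92.93 kcal) are mutually inconsistent,
  so the fixture reproduces each printed margin at its own level, and the
  exact accounting identity is asserted only on simulated data. The
  within-participant placement of accepted offers is unpublished and is
  filled in deterministically (round-robin, every accepter holding at
  least one accepted offer); all descriptive statistics depend only on
  the margins.

```{r}
descriptives(build_paper_counts_fixture())
```

## Problem sizes used by the test suite

The package's own validation runs at sizes chosen to give stable
Monte-Carlo behaviour: 1000 random catalogs against a brute-force filter
oracle; 200 replicate trials at n = 900 for coverage of known age and
frame effects (expected 90–99% for nominal 95% intervals, the small
deficit reflecting the deliberately ignored random intercept in the
fixed-effect fallback); 200 replicates for type-I calibration of the frame
tests at the .025 family threshold; and 2000 replicates for power-oracle
agreement.

## Known limitations

* Gender is modelled as binary because the emulated questionnaire offered
  two options.
* Fixed-effect acceptance models understate standard errors slightly
  under within-shopper correlation; the package reproduces this property
  of the original analysis rather than hiding it.
* The catalog generator produces statistically structured, not
  commercially realistic, product data; prices, weights and densities are
  calibrated only to make the eligibility geometry and basket energy
  scales sensible.
* Re-ingesting the original study's deposited spreadsheets is supported
  only insofar as externally prepared offer/basket tables matching the
  documented CSV schemas can be analysed; no adapter for the raw files is
  shipped or tested.
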