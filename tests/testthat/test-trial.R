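# Randomisation, exclusions, end-to-end trial orchestration, fixture counts.

test_that("permuted-block randomisation balances arms exactly", {
  p9 <- data.frame(participant_id = sprintf("P%d", 1:9))
  expect_equal(unname(table(randomize(p9, seed = 1))), rep(3L, 3L),
               ignore_attr = TRUE)
  p900 <- data.frame(participant_id = sprintf("P%d", 1:900))
  expect_equal(sort(unname(c(table(randomize(p900, seed = 3))))),
               rep(300L, 3L))
  sizes <- table(randomize(data.frame(x = 1:10), seed = 2))
  expect_lte(diff(range(sizes)), 1L)
  expect_identical(randomize(p900, seed = 5), randomize(p900, seed = 5))
  expect_error(randomize(data.frame()), "empty cohort")
})

test_that("exclusion rules fire in printed order with first-hit attribution", {
  parts <- data.frame(
    participant_id = sprintf("P%d", 1:6),
    age = c(30, 30, 30, NA, 30, 30),
    gender = "female", bmi = c(25, 25, 17.5, 25, 25, 25),
    education = "bachelors",
    income = c("under_15500", "under_15500", "under_15500", "under_15500",
               NA, "under_15500"),
    n_items = c(9L, 12L, 12L, 12L, 12L, 12L),
    n_off_list = c(0L, 3L, 0L, 0L, 0L, 0L),
    n_offers = c(2L, 2L, 2L, 2L, 2L, 0L),
    stringsAsFactors = FALSE
  )
  ds <- apply_exclusions(list(participants = parts))
  got <- ds$participants$exclusion_reason
  expect_identical(got, c("fewer_than_10_products", "more_than_two_off_list",
                          "bmi_below_18", "missing_demographics",
                          "missing_demographics", "no_eligible_products"))
  expect_identical(ds$participants$included, rep(FALSE, 6L))

  # first-hit: a short basket with low BMI is attributed to the basket rule
  parts2 <- parts[1, ]
  parts2$bmi <- 15
  expect_identical(
    apply_exclusions(list(participants = parts2))$participants$exclusion_reason,
    "fewer_than_10_products")

  # a clean participant stays in and the ledger conserves counts
  clean <- parts[1, ]
  clean$n_items <- 12L
  both <- rbind(parts, clean)
  ds2 <- apply_exclusions(list(participants = both))
  expect_equal(sum(ds2$exclusions$n), sum(!ds2$participants$included))
  expect_true(ds2$participants$included[7L])
  expect_true(is.na(ds2$participants$exclusion_reason[7L]))
})

test_that("run_trial is deterministic and internally consistent", {
  cfg <- cohort_config(n_participants = 150L)
  td <- run_trial(cfg, seed = 31)
  td2 <- run_trial(cfg, seed = 31)
  expect_identical(td$participants, td2$participants)
  expect_identical(td$offers, td2$offers)
  expect_identical(td$baskets, td2$baskets)

  p <- td$participants
  # ledger conservation
  expect_equal(sum(p$included) + sum(td$exclusions$n), nrow(p))
  # every included participant has at least one offer
  expect_true(all(p$n_offers[p$included] >= 1L))
  # offer count never exceeds basket size
  expect_true(all(p$n_offers <= p$n_items))
  # every offer belongs to an enrolled participant, basket rows to included only
  expect_true(all(td$offers$participant_id %in% p$participant_id))
  expect_setequal(td$baskets$participant_id, p$participant_id[p$included])

  # accounting identities: final = baseline + sum of observed deltas,
  # potential = baseline + sum of potential deltas
  obs <- tapply(td$offers$observed_delta_kcal, td$offers$participant_id, sum)
  pot <- tapply(td$offers$potential_delta_kcal, td$offers$participant_id, sum)
  b <- td$baskets
  obs_b <- as.numeric(ifelse(is.na(obs[b$participant_id]), 0,
                             obs[b$participant_id]))
  pot_b <- as.numeric(ifelse(is.na(pot[b$participant_id]), 0,
                             pot[b$participant_id]))
  expect_equal(b$final_kcal, b$baseline_kcal + obs_b, tolerance = 1e-9)
  expect_equal(b$potential_kcal, b$baseline_kcal + pot_b, tolerance = 1e-9)

  # every emitted alternative satisfies the eligibility criteria
  o <- td$offers
  idx <- sample.int(nrow(o), 40L)
  for (i in idx) {
    orig <- td$catalog$products[td$catalog$products$product_id == o$original_id[i], ]
    alt <- td$catalog$products[td$catalog$products$product_id == o$alt1_id[i], ]
    expect_true(is_eligible(orig, alt))
  }
})

test_that("trial acceptance rate matches the configured intercept", {
  td <- run_trial(cohort_config(), params = acceptance_params(),
                  seed = 101)
  p <- td$participants
  o <- td$offers[td$offers$participant_id %in%
                   p$participant_id[p$included], ]
  rate <- mean(o$accepted)
  # marginal rate under the random intercept (sd 0.5) plus the age effect
  # (0.02 per year, age sd ~15.5) is slightly above plogis(qlogis(0.13));
  # exact binomial 99% interval around that marginal
  sd_eta <- sqrt(0.5^2 + (0.02 * 15.5)^2)
  marginal <- mean(plogis(qlogis(0.13) + qnorm(seq(0.0005, 0.9995, 0.001)) * sd_eta))
  ci <- qbinom(c(0.005, 0.995), nrow(o), marginal) / nrow(o)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("zero-noise configurations produce zero exclusions", {
  cfg <- cohort_config(n_participants = 60L, short_basket_rate = 0,
                       off_list_rate = 0, low_bmi_rate = 0,
                       missing_demo_rate = 0, eligible_share = 0.5,
                       two_alt_share = 0, products_per_category = 20L)
  td <- run_trial(cfg, seed = 17)
  expect_true(all(td$participants$included))
  expect_equal(sum(td$exclusions$n), 0L)
})

test_that("trial tables survive a CSV round trip", {
  td <- run_trial(cohort_config(n_participants = 40L), seed = 3)
  dir <- withr::local_tempdir()
  write_trial_dataset(td, dir)
  back <- read_trial_dataset(dir)
  expect_equal(back$offers$observed_delta_kcal, td$offers$observed_delta_kcal)
  expect_equal(back$participants$included, td$participants$included)
  expect_equal(back$baskets$baseline_kcal, td$baskets$baseline_kcal)
})

test_that("the printed-counts fixture reproduces its margins", {
  fx <- build_paper_counts_fixture()
  p <- fx$participants
  o <- fx$offers
  expect_equal(nrow(p), 713L)
  expect_equal(unname(table(p$arm)[c("health", "cost", "social_norm")]),
               c(234L, 238L, 241L), ignore_attr = TRUE)
  expect_equal(unname(table(o$frame)[c("health", "cost", "social_norm")]),
               c(741L, 740L, 812L), ignore_attr = TRUE)
  acc <- tapply(o$accepted, o$frame, sum)
  expect_equal(unname(acc[c("health", "cost", "social_norm")]),
               c(106L, 85L, 107L), ignore_attr = TRUE)
  # accepters per arm, each holding at least one accepted offer
  accepters <- tapply(p$n_accepted > 0, p$arm, sum)
  expect_equal(unname(accepters[c("health", "cost", "social_norm")]),
               c(78L, 58L, 66L), ignore_attr = TRUE)
  expect_true(all(p$n_offers >= 1L))
  expect_true(all(p$n_accepted <= p$n_offers))
  expect_equal(sum(o$n_alternatives == 2L), 1516L)
  # printed basket margins: baseline mean/SD and the constant potential drop
  b <- fx$baskets
  expect_equal(mean(b$baseline_kcal), 3622.85)
  expect_equal(sd(b$baseline_kcal), 747.80, tolerance = 1e-4)
  expect_equal(b$baseline_kcal - b$potential_kcal, rep(494.97, 713L))
  # observed accounting identity holds inside the fixture
  obs <- tapply(o$observed_delta_kcal, o$participant_id, sum)
  expect_equal(b$final_kcal - b$baseline_kcal,
               as.numeric(obs[b$participant_id]), tolerance = 1e-9)
  # per-offer printed means
  expect_equal(mean(o$observed_delta_kcal), -9.69)
  expect_equal(mean(o$potential_delta_kcal), -92.93)
})
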