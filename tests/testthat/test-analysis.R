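# Descriptives, model kernels against closed-form/grid oracles, paired
# tests, balance checks, Bonferroni thresholds.

test_that("descriptives reproduce exact counts and handle edge cases", {
  fx <- build_paper_counts_fixture()
  d <- descriptives(fx)
  by <- d$by_arm
  expect_equal(by$offers, c(741L, 740L, 812L))
  expect_equal(by$accepted, c(106L, 85L, 107L))
  expect_equal(round(by$acceptance_pct, 2), c(14.30, 11.49, 13.18))
  expect_equal(round(by$accepting_pct, 1), c(33.3, 24.4, 27.4))
  expect_equal(round(d$overall$accepting_pct, 1), 28.3)
  expect_equal(d$baskets$mean_potential_reduction_kcal, 494.97)

  # a single accepted offer is 100%
  one <- list(participants = data.frame(participant_id = "P1", arm = "health",
                                        included = TRUE),
              offers = data.frame(participant_id = "P1", frame = "health",
                                  accepted = TRUE,
                                  observed_delta_kcal = -5,
                                  potential_delta_kcal = -5),
              baskets = NULL)
  class(one) <- "trial_data"
  expect_equal(descriptives(one)$overall$acceptance_pct, 100)

  none <- one
  none$offers <- none$offers[0, ]
  expect_error(descriptives(none), "no offers")
})

test_that("intercept-only logistic fit equals the logit of the proportion", {
  fx <- build_paper_counts_fixture()
  fit <- fit_acceptance_model(fx, intercept_only = TRUE)
  expect_equal(fit$terms$estimate, qlogis(mean(fx$offers$accepted)),
               tolerance = 1e-6)
})

test_that("logistic MLE matches a brute-force likelihood grid search", {
  set.seed(42)
  x <- rnorm(30)
  y <- rbinom(30, 1, plogis(-1 + 0.8 * x))
  df <- data.frame(
    participant_id = sprintf("P%d", 1:30), accepted = y == 1,
    frame = "health", n_alternatives = x, n_offers_for_participant = 1
  )
  # the package model with one control and no frame variation reduces to
  # accepted ~ n_alternatives
  fit <- suppressWarnings(fit_acceptance_model(df))
  est <- coef(fit)[c("(Intercept)", "n_alternatives")]
  oracle <- grid_mle_logit(y, x)
  expect_equal(unname(est), oracle, tolerance = 1e-3)
})

test_that("degenerate and separated acceptance data raise diagnostics", {
  df <- data.frame(participant_id = sprintf("P%d", 1:20), accepted = FALSE,
                   frame = "health", n_alternatives = 1,
                   n_offers_for_participant = 1)
  expect_error(fit_acceptance_model(df), "every offer was kept")
  sep <- df
  sep$accepted <- sep$n_alternatives <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_error(suppressWarnings(fit_acceptance_model(sep)), "separation")
})

test_that("adjusted model carries the planned term structure and fallback flag", {
  td <- run_trial(cohort_config(n_participants = 300L), seed = 77)
  fit <- fit_acceptance_model(td, adjusted = TRUE)
  terms <- fit$terms$term
  expect_true(all(c("age", "bmi", "gendermale", "framecost",
                    "framesocial_norm", "n_alternatives",
                    "n_offers_for_participant",
                    "shopping_responsibilityfull") %in% terms))
  expect_equal(sum(grepl("^frame.*:income|^income.*:frame|:income", terms)), 6L)
  expect_equal(sum(grepl("^education", terms)), 5L)
  expect_equal(fit$family_alpha, 0.025)
  expect_type(fit$fallback, "logical")
  # the unadjusted specification stays fixed-effect by default
  fit_u <- fit_acceptance_model(td)
  expect_false(fit_u$fallback)
  expect_s3_class(fit_u$fit, "glm")
})

test_that("energy-change time coefficient equals the mean per-offer delta", {
  # two-offer toy: deltas -40 and -10, mean -25; single participant forces
  # the documented fixed-effect fallback path
  toy <- list(
    participants = data.frame(participant_id = "P1", arm = "health",
                              included = TRUE),
    offers = data.frame(
      offer_id = c("o1", "o2"), participant_id = "P1", frame = "health",
      accepted = TRUE, n_alternatives = 1L, n_offers_for_participant = 2L,
      original_kcal = c(400, 300), observed_delta_kcal = c(-40, -10),
      potential_delta_kcal = c(-50, -20)),
    baskets = NULL)
  class(toy) <- "trial_data"
  fit <- fit_energy_change_model(toy, "original_vs_final")
  expect_true(fit$fallback)
  expect_equal(coef(fit)[["time"]], -25)
  fit_pot <- fit_energy_change_model(toy, "original_vs_alternative")
  expect_equal(coef(fit_pot)[["time"]], -35)

  # identical kcal at both time points: time coefficient exactly zero
  flat <- toy
  flat$offers$observed_delta_kcal <- 0
  expect_equal(coef(fit_energy_change_model(flat, "original_vs_final"))[["time"]],
               0, tolerance = 1e-12)

  # malformed long table: an offer missing one time row
  long <- energy_long(toy, "original_vs_final")
  expect_error(fit_energy_change_model(long[-1, ]), "one row per time level")
})

test_that("multilevel energy model recovers the simulated reduction", {
  td <- run_trial(cohort_config(n_participants = 400L), seed = 13)
  fit <- fit_energy_change_model(td, "original_vs_final")
  o <- merge(td$offers, td$participants[, c("participant_id", "included")])
  true_mean <- mean(o$observed_delta_kcal[o$included])
  expect_equal(coef(fit)[["time"]], true_mean, tolerance = 1e-6)
  expect_true(fit$terms$p[fit$terms$term == "time"] > 0 &&
                fit$terms$p[fit$terms$term == "time"] < 1)
  # the all-accepted counterfactual reduction is large and unambiguous
  fit_pot <- fit_energy_change_model(td, "original_vs_alternative")
  expect_lt(fit_pot$terms$p[fit_pot$terms$term == "time"], 0.025)
  expect_lt(coef(fit_pot)[["time"]], -20)
  # frame moderation terms appear when requested
  fitf <- fit_energy_change_model(td, "original_vs_final", by_frame = TRUE)
  expect_true(all(c("time:framecost", "time:framesocial_norm") %in%
                    fitf$terms$term))
})

test_that("paired t-tests equal their closed forms and flag degenerate input", {
  mk <- function(diffs) {
    data.frame(participant_id = seq_along(diffs), arm = "health",
               baseline_kcal = 1000, final_kcal = 1000 + diffs,
               potential_kcal = 1000 + diffs - 1)
  }
  res <- basket_change_tests(mk(c(1, 2, 3)))
  expect_equal(unname(res$kcal_observed$terms$statistic), 2 * sqrt(3),
               tolerance = 1e-12)
  expect_equal(unname(res$kcal_observed$terms$df), 2)
  expect_equal(res$kcal_observed$family_alpha, 0.05 / 3)

  sym <- basket_change_tests(mk(c(-1, 1)))
  expect_equal(unname(sym$kcal_observed$terms$statistic), 0)
  expect_equal(sym$kcal_observed$terms$p, 1)

  expect_error(basket_change_tests(mk(c(0, 0, 0))), "zero variance")
})

test_that("basket regression matches a saturated hand fit and validates input", {
  b <- data.frame(participant_id = c("P1", "P2"),
                  arm = c("health", "cost"),
                  baseline_kcal = c(1000, 1000),
                  final_kcal = c(980, 950),
                  potential_kcal = c(900, 900))
  fit <- basket_change_regression(b)
  expect_equal(unname(coef(fit)[["armcost"]]), -30) # (-50) - (-20)
  expect_equal(unname(coef(fit)[["(Intercept)"]]), -20)
  flat <- b
  flat$final_kcal <- flat$baseline_kcal
  expect_error(basket_change_regression(flat), "zero variance")
})

test_that("balance checks use the textbook chi-square and F statistics", {
  # perfectly balanced 3 x 2 table: chi-square exactly 0, p = 1
  p_bal <- data.frame(
    participant_id = sprintf("P%d", 1:60),
    arm = rep(c("health", "cost", "social_norm"), each = 20),
    gender = rep(rep(c("female", "male"), each = 10), 3),
    age = rep(c(rep(30, 10), rep(50, 10)), 3),
    included = TRUE
  )
  res <- balance_checks(p_bal)
  expect_equal(res$statistic[res$variable == "gender"], 0)
  expect_equal(res$p[res$variable == "gender"], 1)
  expect_equal(res$statistic[res$variable == "age"], 0, tolerance = 1e-12)

  # hand-built 3 x 2 table: chi-square = sum (O - E)^2 / E
  counts <- rbind(c(12, 8), c(10, 10), c(6, 14))
  p_hand <- data.frame(
    participant_id = sprintf("Q%d", 1:60),
    arm = rep(c("health", "cost", "social_norm"), times = rowSums(counts)),
    gender = as.vector(mapply(function(f, m) rep(c("female", "male"), c(f, m)),
                              counts[, 1], counts[, 2])),
    included = TRUE
  )
  exp_counts <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi_by_hand <- sum((counts - exp_counts)^2 / exp_counts)
  res2 <- balance_checks(p_hand)
  expect_equal(res2$statistic[res2$variable == "gender"], chi_by_hand)

  expect_error(balance_checks(data.frame(arm = "health", gender = "female",
                                         included = TRUE)),
               "two arms")
})

test_that("Bonferroni thresholds reproduce the reported families", {
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(round(bonferroni_alpha(0.05, 3), 3), 0.017)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "positive integer")
})
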