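# Synthetic study-condition generator: product catalogs with category
# structure rich enough for the swap filter to fire, shopper cohorts whose
# marginals match the trial's baseline table, 12-item shopping behaviour with
# configurable noise driving the exclusion rules, and a logistic acceptance
# process with a participant-level random intercept.

education_levels <- c("none", "up_to_4_gcses", "5_plus_gcses",
                      "2_plus_a_levels", "bachelors", "postgraduate")
income_levels <- c("under_15500", "15500_24999", "25000_39999", "40000_plus")
frame_levels <- c("health", "cost", "social_norm")

default_categories <- c(
  "sweet_biscuits", "cheddar_cheese", "fresh_soup", "crisps", "yogurt",
  "breakfast_cereal", "sliced_bread", "chocolate_bars", "ready_meals",
  "fizzy_drinks", "fruit_juice", "ice_cream", "sausages", "pasta_sauce",
  "savoury_snacks", "cakes", "frozen_pizza", "sandwich_fillers", "dips",
  "cooking_sauces"
)

#' Cohort and catalog configuration
#'
#' Defaults encode the trial's study conditions: 900 shoppers whose age,
#' gender, BMI, education and income marginals match the trial's baseline
#' table; a 12-slot shopping list (9 targeted categories + 3 open-ended
#' slots); a catalog tuned so roughly a quarter of products have an eligible
#' lower-energy partner (giving ~3.2 swap offers per 12-item basket); and
#' noise rates matching the observed frequencies of the five exclusion
#' rules.
#'
#' @param n_participants Cohort size (default 900).
#' @param age_mean,age_sd,age_range Age distribution: truncated normal on
#'   `age_range`, internally recentred so the post-truncation mean equals
#'   `age_mean` (defaults 47.7, 15.9, 18-97).
#' @param female_share Probability of gender `"female"` (default 0.52).
#' @param bmi_mean,bmi_sd,bmi_range Truncated-normal BMI for shoppers above
#'   the screening floor (defaults 27.2, 6.3, 18-40).
#' @param education_probs,income_probs Marginal probabilities over the 6
#'   education and 4 income levels (defaults: the trial's pooled baseline
#'   shares).
#' @param full_responsibility_share Probability of full (vs half) grocery
#'   responsibility (default 0.65).
#' @param categories Shelf-category taxonomy for the generated catalog.
#' @param products_per_category Products per category (default 15; must be
#'   >= 2).
#' @param eligible_share Target share of products that have at least one
#'   eligible lower-energy alternative under default criteria (default
#'   0.26). Guaranteed by construction: each category holds weight-matched,
#'   slightly cheaper, lower-density partner products.
#' @param two_alt_share Share of swap-target products given two eligible
#'   partners instead of one (default 0.67, the observed share of offers
#'   showing two alternatives), so checkout offers mix one- and
#'   two-alternative presentations.
#' @param price_range,density_filler_range,density_target_range Uniform
#'   ranges for prices (GBP) and energy densities (kcal/100 g) of ordinary
#'   ("filler") and swap-target products.
#' @param weight_base,weight_band_ratio Pack-weight bands: band b is centred
#'   at `weight_base * weight_band_ratio^(b-1)` grams. The ratio (default
#'   1.25) keeps distinct bands outside each other's 90-110% window so the
#'   eligible share is exact.
#' @param n_targeted_slots,n_open_slots Shopping-list design: fixed-category
#'   slots and open-ended slots resolved per shopper (defaults 9 + 3 = 12).
#' @param short_basket_rate Probability a shopper checks out with fewer than
#'   10 items (default 0.126, the observed rate of exclusion rule i).
#' @param off_list_rate Probability a shopper swaps more than two items for
#'   off-list products (default 0.022, rule ii).
#' @param low_bmi_rate Probability of a self-reported BMI below 18 (default
#'   0.024, rule iii).
#' @param missing_demo_rate Probability of missing demographic data
#'   (default 0.0033, rule iv).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 900L,
                          age_mean = 47.7, age_sd = 15.9, age_range = c(18, 97),
                          female_share = 0.52,
                          bmi_mean = 27.2, bmi_sd = 6.3, bmi_range = c(18, 40),
                          education_probs = c(0.025, 0.137, 0.180, 0.222, 0.285, 0.151),
                          income_probs = c(0.165, 0.215, 0.289, 0.331),
                          full_responsibility_share = 0.65,
                          categories = default_categories,
                          products_per_category = 15L,
                          eligible_share = 0.26,
                          two_alt_share = 0.67,
                          price_range = c(0.8, 4.0),
                          density_filler_range = c(60, 240),
                          density_target_range = c(250, 480),
                          weight_base = 80, weight_band_ratio = 1.25,
                          n_targeted_slots = 9L, n_open_slots = 3L,
                          short_basket_rate = 0.126,
                          off_list_rate = 0.022,
                          low_bmi_rate = 0.024,
                          missing_demo_rate = 0.0033) {
  if (!is_count(n_participants)) fail("n_participants must be a positive integer")
  rates <- c(short_basket_rate, off_list_rate, low_bmi_rate, missing_demo_rate,
             female_share, full_responsibility_share, eligible_share,
             two_alt_share)
  if (!all(vapply(rates, is_prob, logical(1L)))) {
    fail("all rates and shares must be probabilities in [0, 1]")
  }
  if (length(education_probs) != length(education_levels) ||
      abs(sum(education_probs) - 1) > 1e-6) {
    fail("education_probs must be %d probabilities summing to 1",
         length(education_levels))
  }
  if (length(income_probs) != length(income_levels) ||
      abs(sum(income_probs) - 1) > 1e-6) {
    fail("income_probs must be %d probabilities summing to 1",
         length(income_levels))
  }
  if (n_targeted_slots + n_open_slots != 12L) {
    fail("the shopping list must have exactly 12 slots")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic product catalog
#'
#' Each category holds `products_per_category` products arranged in pack
#' weight bands. A share `eligible_share` of them are "targets": high-density
#' products paired with a partner in the same weight band that is 5% lighter
#' to 5% heavier, 2-18% cheaper, and 30-80 kcal/100 g less energy dense, so
#' the partner is an eligible swap for the target under default criteria.
#' Distinct bands are separated by more than the 90-110% weight window, so
#' the share of products with at least one eligible alternative is exactly
#' the number of targets per category (round of `eligible_share *
#' products_per_category`) over `products_per_category`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the catalog is deterministic given
#'   `(config, seed)`.
#' @return A `swap_catalog`.
#' @export
generate_catalog <- function(config = cohort_config(), seed = 1L) {
  k <- as.integer(config$products_per_category)
  if (k < 2L) fail("infeasible catalog: need at least 2 products per category")
  m <- as.integer(round(config$eligible_share * k))
  p2 <- as.integer(round(config$two_alt_share * m))
  if (2L * m + p2 > k) {
    fail("infeasible catalog: eligible_share %.2f with two_alt_share %.2f needs %d target+partner products but the category holds %d",
         config$eligible_share, config$two_alt_share, 2L * m + p2, k)
  }
  if (config$density_target_range[1] < 50 && m > 0L) {
    fail("infeasible catalog: target density floor too low for the partner reduction")
  }
  # worst-case adjacent-band weight ratio must clear the 110% window
  if (config$weight_band_ratio * 0.95 / 1.05 <= 1.10 && m > 0L) {
    fail("infeasible catalog: weight_band_ratio too small to separate bands")
  }
  set.seed(seed)
  n_fill <- k - 2L * m - p2
  n_bands <- m + n_fill # one band per target (with its partners), one per filler
  tgt_of <- c(seq_len(m), seq_len(p2)) # partner j belongs to target tgt_of[j]
  n_par <- m + p2
  rows <- vector("list", length(config$categories))
  for (ci in seq_along(config$categories)) {
    cat_name <- config$categories[ci]
    band_w <- config$weight_base * config$weight_band_ratio^(seq_len(n_bands) - 1L)
    id <- function(j) sprintf("p_%02d_%02d", ci, j)
    target <- data.frame(
      product_id = id(seq_len(m)),
      name = sprintf("%s target %d", cat_name, seq_len(m)),
      shelf_category = rep(cat_name, m),
      price_gbp = round(stats::runif(m, 1.2, config$price_range[2]), 2),
      pack_weight_g = round(band_w[seq_len(m)], 1),
      energy_kcal_per_100g = round(stats::runif(
        m, config$density_target_range[1], config$density_target_range[2]), 1),
      stringsAsFactors = FALSE
    )
    # partner reductions are drawn from [30, 50] kcal/100 g so two partners
    # of one target never differ by the eligibility threshold themselves
    partner <- data.frame(
      product_id = id(m + seq_len(n_par)),
      name = sprintf("%s light %d", cat_name, seq_len(n_par)),
      shelf_category = rep(cat_name, n_par),
      price_gbp = round(target$price_gbp[tgt_of] * stats::runif(n_par, 0.82, 0.98), 2),
      pack_weight_g = round(target$pack_weight_g[tgt_of] *
                              stats::runif(n_par, 0.95, 1.05), 1),
      energy_kcal_per_100g = round(
        target$energy_kcal_per_100g[tgt_of] - stats::runif(n_par, 30, 50), 1),
      stringsAsFactors = FALSE
    )
    filler <- data.frame(
      product_id = id(m + n_par + seq_len(n_fill)),
      name = sprintf("%s item %d", cat_name, seq_len(n_fill)),
      shelf_category = rep(cat_name, n_fill),
      price_gbp = round(stats::runif(n_fill, config$price_range[1],
                                     config$price_range[2]), 2),
      pack_weight_g = round(band_w[m + seq_len(n_fill)], 1),
      energy_kcal_per_100g = round(stats::runif(
        n_fill, config$density_filler_range[1], config$density_filler_range[2]), 1),
      stringsAsFactors = FALSE
    )
    cat_rows <- rbind(target, partner, filler)
    # per-pack nutrients; partners carry less saturated fat and slightly
    # less sugar than their target, mirroring lower energy density
    base_fat <- stats::runif(k, 0.5, 15)
    base_sugar <- stats::runif(k, 1, 40)
    base_salt <- stats::runif(k, 0.05, 3)
    if (m > 0L) {
      pidx <- m + seq_len(n_par)
      base_fat[pidx] <- base_fat[tgt_of] * stats::runif(n_par, 0.5, 0.9)
      base_sugar[pidx] <- base_sugar[tgt_of] * stats::runif(n_par, 0.7, 1.05)
      base_salt[pidx] <- base_salt[tgt_of] * stats::runif(n_par, 0.85, 1.15)
    }
    cat_rows$sat_fat_g_per_pack <- round(base_fat, 2)
    cat_rows$sugar_g_per_pack <- round(base_sugar, 2)
    cat_rows$salt_g_per_pack <- round(base_salt, 2)
    rows[[ci]] <- cat_rows
  }
  products <- do.call(rbind, rows)
  rownames(products) <- NULL
  catalog(products, taxonomy = config$categories)
}

# partner prices: runif(0.82, 0.98) keeps the partner strictly cheaper and
# within the 20% reduction cap even after both sides are rounded to whole
# pence (target prices are >= 1.20 GBP, so the 2% margins exceed half a
# penny); generated catalogs are re-validated by construction via catalog().

#' Generate a synthetic shopper cohort
#'
#' Draws demographics from the configured marginals. Age and BMI are
#' truncated normals (age recentred so its post-truncation mean equals the
#' configured mean); a `low_bmi_rate` fraction of shoppers report BMI below
#' 18 and a `missing_demo_rate` fraction lack income data, feeding exclusion
#' rules (iii) and (iv).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A data.frame with one row per participant: `participant_id`,
#'   `age`, `gender`, `bmi`, `education`, `income`,
#'   `shopping_responsibility`, `arm` (unassigned, `NA`), `included`
#'   (`NA` until exclusions are applied) and `exclusion_reason`.
#' @export
generate_participants <- function(config = cohort_config(), seed = 1L) {
  n <- as.integer(config$n_participants)
  set.seed(seed)
  mu <- truncnorm_recentre(config$age_mean, config$age_sd, config$age_range)
  age <- round(rtruncnorm(n, mu, config$age_sd, config$age_range))
  gender <- ifelse(stats::runif(n) < config$female_share, "female", "male")
  low_bmi <- stats::runif(n) < config$low_bmi_rate
  bmi <- rtruncnorm(n, config$bmi_mean, config$bmi_sd, config$bmi_range)
  bmi[low_bmi] <- stats::runif(sum(low_bmi), 15, 17.9)
  education <- sample(education_levels, n, replace = TRUE,
                      prob = config$education_probs)
  income <- sample(income_levels, n, replace = TRUE, prob = config$income_probs)
  income[stats::runif(n) < config$missing_demo_rate] <- NA_character_
  resp <- ifelse(stats::runif(n) < config$full_responsibility_share,
                 "full", "half")
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = age,
    gender = gender,
    bmi = round(bmi, 1),
    education = education,
    income = income,
    shopping_responsibility = resp,
    arm = NA_character_,
    included = NA,
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

# mean of N(mu, sd) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, range) {
  a <- (range[1] - mu) / sd
  b <- (range[2] - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# pick mu so that the truncated mean equals `target`
truncnorm_recentre <- function(target, sd, range) {
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, range) - target,
                 lower = target - 3 * sd, upper = target + 3 * sd)$root
}

# inverse-CDF truncated normal sampler (exact, no rejection)
rtruncnorm <- function(n, mu, sd, range) {
  lo <- stats::pnorm(range[1], mu, sd)
  hi <- stats::pnorm(range[2], mu, sd)
  stats::qnorm(stats::runif(n, lo, hi), mu, sd)
}

#' Default 12-slot shopping-list design
#'
#' Nine targeted slots tied to fixed shelf categories (spread across the
#' taxonomy) and three open-ended slots whose category is resolved per
#' shopper at shopping time.
#'
#' @param cat A `swap_catalog`.
#' @param config A [cohort_config()].
#' @return data.frame with columns `slot`, `category` (`NA` for open-ended
#'   slots) and `open_ended`.
#' @export
default_list_design <- function(cat, config = cohort_config()) {
  n_t <- as.integer(config$n_targeted_slots)
  n_o <- as.integer(config$n_open_slots)
  if (n_t > length(cat$taxonomy)) {
    fail("list design needs %d targeted categories but the taxonomy has %d",
         n_t, length(cat$taxonomy))
  }
  targeted <- cat$taxonomy[round(seq(1L, length(cat$taxonomy), length.out = n_t))]
  data.frame(
    slot = seq_len(n_t + n_o),
    category = c(targeted, rep(NA_character_, n_o)),
    open_ended = c(rep(FALSE, n_t), rep(TRUE, n_o)),
    stringsAsFactors = FALSE
  )
}

#' Simulate one shopper's basket
#'
#' Picks a product uniformly at random from each listed category (open-ended
#' slots resolve to a random category first). With probability
#' `short_basket_rate` the shopper checks out with only 4-9 items; with
#' probability `off_list_rate` they replace 3-5 items with off-list products
#' from other categories. Draws come from a substream keyed by the
#' participant id, so baskets are reproducible per shopper under the master
#' seed.
#'
#' @param participant A one-row slice of the participants table.
#' @param cat A `swap_catalog`.
#' @param config A [cohort_config()] supplying the noise rates.
#' @param seed Master seed.
#' @param list_design Shopping-list design; defaults to
#'   [default_list_design()].
#' @return A `swap_basket`.
#' @export
simulate_shopping <- function(participant, cat, config = cohort_config(),
                              seed = 1L, list_design = NULL) {
  if (is.null(list_design)) list_design <- default_list_design(cat, config)
  listed <- list_design$category[!list_design$open_ended]
  missing_cat <- setdiff(listed, cat$products$shelf_category)
  if (length(missing_cat)) {
    fail("shopping-list category absent from catalog: %s",
         paste(missing_cat, collapse = ", "))
  }
  pid <- participant$participant_id
  set.seed(substream_seed(seed, paste0("shop:", pid)))
  by_cat <- split(cat$products$product_id, cat$products$shelf_category)
  u_short <- stats::runif(1L)
  u_off <- stats::runif(1L)
  cats <- list_design$category
  open <- list_design$open_ended
  cats[open] <- sample(cat$taxonomy, sum(open), replace = TRUE)
  picks <- vapply(cats, function(cc) {
    ids <- by_cat[[cc]]
    ids[sample.int(length(ids), 1L)]
  }, character(1L))
  items <- data.frame(slot = list_design$slot, product_id = picks,
                      on_list = TRUE, stringsAsFactors = FALSE)
  if (u_off < config$off_list_rate) {
    n_off <- sample(3:5, 1L)
    repl <- sample.int(nrow(items), n_off)
    items$product_id[repl] <- cat$products$product_id[
      sample.int(nrow(cat$products), n_off)]
    items$on_list[repl] <- FALSE
  }
  if (u_short < config$short_basket_rate) {
    n_keep <- sample(4:9, 1L)
    items <- items[sort(sample.int(nrow(items), n_keep)), , drop = FALSE]
  }
  basket(pid, items)
}

#' Acceptance-model parameters
#'
#' The generator's acceptance process is the logistic model the trial's
#' analysis assumes: on the log-odds scale, an intercept (the acceptance
#' rate of an average-age shopper in the health arm), frame offsets, a
#' linear age effect centred at `age_center`, an income-by-frame interaction
#' and a participant-level random intercept capturing within-shopper
#' correlation of repeated decisions.
#'
#' @param intercept Log-odds of acceptance at the reference levels; default
#'   `qlogis(0.13)`, calibrated to the ~13% headline acceptance rate.
#' @param beta_cost,beta_social Frame offsets (log-odds); default 0, the
#'   trial's null result.
#' @param beta_age Log-odds per year of age (default 0.02).
#' @param beta_income_x_frame 4 x 3 matrix (income band x frame) of
#'   interaction offsets; default all zero. The health column is the
#'   reference and should stay 0.
#' @param random_intercept_sd SD of the participant random intercept
#'   (log-odds; default 0.5, a mild within-shopper correlation).
#' @param two_alt_second_share Probability an accepted two-alternative offer
#'   takes the second-ranked product (default 0.5).
#' @param age_center Centring age in years (default 47, the cohort mean).
#' @return An object of class `acceptance_params`.
#' @export
acceptance_params <- function(intercept = stats::qlogis(0.13),
                              beta_cost = 0, beta_social = 0,
                              beta_age = 0.02,
                              beta_income_x_frame = NULL,
                              random_intercept_sd = 0.5,
                              two_alt_second_share = 0.5,
                              age_center = 47) {
  if (is.null(beta_income_x_frame)) {
    beta_income_x_frame <- matrix(0, nrow = length(income_levels),
                                  ncol = length(frame_levels),
                                  dimnames = list(income_levels, frame_levels))
  }
  stopifnot(is.matrix(beta_income_x_frame),
            identical(rownames(beta_income_x_frame), income_levels),
            identical(colnames(beta_income_x_frame), frame_levels))
  if (!is_number(random_intercept_sd) || random_intercept_sd < 0) {
    fail("random_intercept_sd must be non-negative")
  }
  if (!is_prob(two_alt_second_share)) {
    fail("two_alt_second_share must be a probability")
  }
  structure(list(
    intercept = intercept, beta_cost = beta_cost, beta_social = beta_social,
    beta_age = beta_age, beta_income_x_frame = beta_income_x_frame,
    random_intercept_sd = random_intercept_sd,
    two_alt_second_share = two_alt_second_share,
    age_center = age_center
  ), class = "acceptance_params")
}

frame_offset <- function(params, frame) {
  switch(frame, health = 0, cost = params$beta_cost,
         social_norm = params$beta_social,
         fail("unknown frame: %s", frame))
}

#' Probability that a shopper accepts a swap offer
#'
#' Inverse logit of: intercept + frame offset + `beta_age` * (age -
#' `age_center`) + income-by-frame offset + the participant's random
#' intercept. A missing income contributes no interaction term.
#'
#' @param participant One participants-table row (needs `age`, `income`).
#' @param offer A `swap_offer` (supplies the frame).
#' @param params An [acceptance_params()] object.
#' @param random_intercept The participant's log-odds offset (default 0).
#' @return A probability.
#' @export
acceptance_probability <- function(participant, offer,
                                   params = acceptance_params(),
                                   random_intercept = 0) {
  inc <- participant$income
  inter <- if (is.na(inc)) 0 else params$beta_income_x_frame[inc, offer$frame]
  stats::plogis(params$intercept + frame_offset(params, offer$frame) +
                  params$beta_age * (participant$age - params$age_center) +
                  inter + random_intercept)
}

#' Draw a decision for a swap offer
#'
#' Accepts with probability `p`; among accepted two-alternative offers the
#' second-ranked product is chosen with probability
#' `two_alt_second_share`. Uses the current RNG state; seed the session (or
#' a substream) for reproducibility.
#'
#' @param p Acceptance probability.
#' @param offer A `swap_offer`.
#' @param params An [acceptance_params()] object.
#' @return `"keep"`, `"accept_first"` or `"accept_second"`.
#' @export
simulate_decision <- function(p, offer, params = acceptance_params()) {
  if (!is_prob(p)) fail("p must be a probability")
  if (stats::runif(1L) >= p) return("keep")
  if (length(offer$alternative_ids) >= 2L &&
      stats::runif(1L) < params$two_alt_second_share) {
    "accept_second"
  } else {
    "accept_first"
  }
}
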