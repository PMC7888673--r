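# In-silico trial: permuted-block randomisation, end-to-end simulation of
# shopping + checkout offers + decisions, the five exclusion rules with a
# first-hit ledger, analysis-ready tables, and the fixture rebuilt from the
# trial's printed counts.

exclusion_reason_levels <- c(
  "fewer_than_10_products", "more_than_two_off_list", "bmi_below_18",
  "missing_demographics", "no_eligible_products"
)

#' Permuted-block 1:1:1 randomisation
#'
#' Blocks of size `sum(ratio)` each contain the arms in the given ratio, in
#' random order; a partial final block is a random subset. For a cohort
#' divisible by the block size, arm sizes are exactly equal (this is a
#' deliberate divergence from platform randomisation, which only balances in
#' expectation).
#'
#' @param participants Participants data.frame (only its row count is used).
#' @param ratio Integer allocation ratio across the three frames (default
#'   `c(1, 1, 1)`).
#' @param seed Integer seed.
#' @return Character vector of arm assignments (`"health"`, `"cost"`,
#'   `"social_norm"`), one per participant.
#' @export
randomize <- function(participants, ratio = c(1L, 1L, 1L), seed = 1L) {
  n <- nrow(participants)
  if (is.null(n) || n == 0L) fail("cannot randomise an empty cohort")
  if (length(ratio) != 3L || any(ratio < 1) || any(ratio != round(ratio))) {
    fail("ratio must be three positive integers")
  }
  block <- rep(frame_levels, times = ratio)
  set.seed(seed)
  n_full <- n %/% length(block)
  arms <- c(
    unlist(lapply(seq_len(n_full), function(i) sample(block))),
    sample(block)[seq_len(n %% length(block))]
  )
  arms[seq_len(n)]
}

#' Exclusion rules
#'
#' The five participant-level exclusion rules, applied in their published
#' order with first-hit attribution: (i) fewer than `min_products` items
#' bought, (ii) more than `max_off_list` off-list items, (iii) BMI below
#' `min_bmi`, (iv) missing demographic data, (v) no products eligible for a
#' swap offer.
#'
#' @param min_products Minimum basket size (default 10).
#' @param max_off_list Maximum tolerated off-list items (default 2).
#' @param min_bmi Minimum self-reported BMI (default 18).
#' @param require_complete_demographics,require_any_eligible Toggle rules
#'   (iv) and (v).
#' @return An object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(min_products = 10L, max_off_list = 2L,
                            min_bmi = 18,
                            require_complete_demographics = TRUE,
                            require_any_eligible = TRUE) {
  if (!is_count(min_products) || !is_number(min_bmi) || min_bmi <= 0 ||
      !is_number(max_off_list) || max_off_list < 0) {
    fail("exclusion thresholds must be positive")
  }
  structure(list(min_products = min_products, max_off_list = max_off_list,
                 min_bmi = min_bmi,
                 require_complete_demographics = require_complete_demographics,
                 require_any_eligible = require_any_eligible),
            class = "exclusion_rules")
}

#' Apply the exclusion rules to an assembled trial dataset
#'
#' Flags each participant as included or excluded, attributes the first
#' failing rule as the primary exclusion reason, builds the reason ledger,
#' and drops basket rows of excluded participants.
#'
#' @param dataset A `trial_data` object (or a bare list with a
#'   `participants` table carrying `n_items`, `n_off_list`, `bmi`, `age`,
#'   `gender`, `education`, `income` and `n_offers`).
#' @param rules An [exclusion_rules()] object.
#' @return The dataset with `participants$included`/`exclusion_reason`
#'   filled in and an `exclusions` ledger table (reason, n) attached.
#' @export
apply_exclusions <- function(dataset, rules = exclusion_rules()) {
  p <- dataset$participants
  reason <- rep(NA_character_, nrow(p))
  hit <- function(cond, label) ifelse(is.na(reason) & cond, label, reason)
  reason <- hit(p$n_items < rules$min_products, exclusion_reason_levels[1L])
  reason <- hit(p$n_off_list > rules$max_off_list, exclusion_reason_levels[2L])
  reason <- hit(p$bmi < rules$min_bmi, exclusion_reason_levels[3L])
  if (rules$require_complete_demographics) {
    incomplete <- is.na(p$age) | is.na(p$gender) | is.na(p$bmi) |
      is.na(p$education) | is.na(p$income)
    reason <- hit(incomplete, exclusion_reason_levels[4L])
  }
  if (rules$require_any_eligible) {
    reason <- hit(p$n_offers == 0L, exclusion_reason_levels[5L])
  }
  p$included <- is.na(reason)
  p$exclusion_reason <- reason
  dataset$participants <- p
  dataset$exclusions <- data.frame(
    reason = exclusion_reason_levels,
    n = vapply(exclusion_reason_levels,
               function(r) sum(reason == r, na.rm = TRUE), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(dataset$baskets)) {
    dataset$baskets <-
      dataset$baskets[dataset$baskets$participant_id %in%
                        p$participant_id[p$included], , drop = FALSE]
    rownames(dataset$baskets) <- NULL
  }
  dataset
}

new_trial_data <- function(participants, offers, baskets, exclusions = NULL,
                           catalog = NULL, seed = NULL) {
  structure(list(participants = participants, offers = offers,
                 baskets = baskets, exclusions = exclusions,
                 catalog = catalog, seed = seed),
            class = "trial_data")
}

#' @exportS3Method print trial_data
print.trial_data <- function(x, ...) {
  inc <- sum(x$participants$included, na.rm = TRUE)
  cat(sprintf("<trial_data> %d participants (%d included), %d swap offers, %d basket rows\n",
              nrow(x$participants), inc, nrow(x$offers),
              if (is.null(x$baskets)) 0L else nrow(x$baskets)))
  invisible(x)
}

#' @exportS3Method summary trial_data
summary.trial_data <- function(object, ...) descriptives(object)

#' Run the full in-silico trial
#'
#' Generates a catalog and cohort, randomises 1:1:1, simulates each
#' shopper's basket, offers swaps at checkout under the arm's message frame,
#' draws accept/keep decisions from the logistic acceptance model, applies
#' the five exclusion rules, and assembles the three analysis tables
#' (participants, offers, baskets). Fully deterministic given `seed`;
#' participant-level draws use id-keyed substreams.
#'
#' @param config A [cohort_config()].
#' @param criteria A [swap_criteria()] object.
#' @param params An [acceptance_params()] object.
#' @param rules An [exclusion_rules()] object.
#' @param seed Master integer seed.
#' @return A `trial_data` object: `participants` (one row per enrolled
#'   shopper with demographics, arm, basket/offer counts, inclusion flag and
#'   primary exclusion reason), `offers` (one row per swap offer with shown
#'   alternatives, decision, observed and potential kcal deltas, and the
#'   original pack kcal), `baskets` (per included shopper: baseline, final
#'   and all-swaps-accepted potential totals for kcal and the three
#'   nutrients), and the `exclusions` ledger.
#' @export
run_trial <- function(config = cohort_config(), criteria = swap_criteria(),
                      params = acceptance_params(),
                      rules = exclusion_rules(), seed = 1L) {
  cat <- withCallingHandlers(
    generate_catalog(config, seed = substream_seed(seed, "catalog")),
    error = function(e) fail("catalog stage: %s", conditionMessage(e)))
  parts <- generate_participants(config, seed = substream_seed(seed, "participants"))
  parts$arm <- randomize(parts, seed = substream_seed(seed, "randomize"))
  list_design <- default_list_design(cat, config)

  # ranked alternatives once per catalog product (the per-offer algorithm is
  # a pure function of the catalog, so the map is shared by all shoppers)
  prods <- cat$products
  alt_map <- lapply(seq_len(nrow(prods)), function(i) {
    utils::head(rank_alternatives(prods[i, ], cat, criteria)$product_id,
                criteria$max_alternatives_shown)
  })
  names(alt_map) <- prods$product_id
  pack_kcal <- stats::setNames(energy_per_pack(prods), prods$product_id)

  baskets <- lapply(seq_len(nrow(parts)), function(i) {
    simulate_shopping(parts[i, ], cat, config, seed, list_design)
  })
  items <- do.call(rbind, lapply(seq_along(baskets), function(i) {
    b <- baskets[[i]]
    data.frame(participant_id = parts$participant_id[i],
               slot = b$slot, product_id = b$product_id, on_list = b$on_list,
               stringsAsFactors = FALSE)
  }))

  # checkout offers: one per item with at least one eligible alternative
  alts <- alt_map[items$product_id]
  n_alt <- lengths(alts)
  has <- n_alt > 0L
  offers <- data.frame(
    participant_id = items$participant_id[has],
    slot = items$slot[has],
    original_id = items$product_id[has],
    alt1_id = vapply(alts[has], `[`, character(1L), 1L),
    alt2_id = vapply(alts[has], function(a) if (length(a) > 1L) a[2L] else NA_character_,
                     character(1L)),
    n_alternatives = n_alt[has],
    stringsAsFactors = FALSE
  )
  ord <- order(match(offers$participant_id, parts$participant_id), offers$slot)
  offers <- offers[ord, , drop = FALSE]
  offers$offer_id <- stats::ave(offers$participant_id, offers$participant_id,
                                FUN = function(x) sprintf("%s_o%d", x, seq_along(x)))
  pidx <- match(offers$participant_id, parts$participant_id)
  offers$frame <- parts$arm[pidx]

  # participant random intercepts from id-keyed substreams
  ri <- vapply(parts$participant_id, function(pid) {
    set.seed(substream_seed(seed, paste0("ri:", pid)))
    stats::rnorm(1L, 0, params$random_intercept_sd)
  }, numeric(1L))

  inc <- parts$income[pidx]
  inter <- ifelse(is.na(inc), 0,
                  params$beta_income_x_frame[cbind(ifelse(is.na(inc), 1L,
                                                          match(inc, income_levels)),
                                                   match(offers$frame, frame_levels))])
  eta <- params$intercept +
    vapply(offers$frame, function(f) frame_offset(params, f), numeric(1L)) +
    params$beta_age * (parts$age[pidx] - params$age_center) + inter + ri[pidx]
  p_accept <- stats::plogis(eta)

  set.seed(substream_seed(seed, "decisions"))
  u1 <- stats::runif(nrow(offers))
  u2 <- stats::runif(nrow(offers))
  accepted <- u1 < p_accept
  second <- accepted & offers$n_alternatives == 2L & u2 < params$two_alt_second_share
  offers$decision <- ifelse(!accepted, "keep",
                            ifelse(second, "accept_second", "accept_first"))
  offers$accepted <- accepted
  chosen <- ifelse(accepted, ifelse(second, offers$alt2_id, offers$alt1_id),
                   offers$original_id)
  offers$original_kcal <- unname(pack_kcal[offers$original_id])
  offers$observed_delta_kcal <- unname(pack_kcal[chosen]) - offers$original_kcal
  offers$potential_delta_kcal <- unname(pack_kcal[offers$alt1_id]) - offers$original_kcal

  n_offers <- stats::setNames(rep(0L, nrow(parts)), parts$participant_id)
  tab <- table(offers$participant_id)
  n_offers[names(tab)] <- as.integer(tab)
  offers$n_offers_for_participant <- unname(n_offers[offers$participant_id])

  # basket totals: baseline as chosen, final after decisions, potential with
  # every offer's top-ranked alternative substituted
  key <- paste(items$participant_id, items$slot)
  okey <- paste(offers$participant_id, offers$slot)
  final_id <- items$product_id
  final_id[match(okey, key)] <- chosen
  potential_id <- items$product_id
  potential_id[match(okey, key)] <- offers$alt1_id
  totals <- function(ids, label) {
    p <- get_products(cat, ids)
    agg <- rowsum(cbind(kcal = energy_per_pack(p),
                        sat_fat_g = p$sat_fat_g_per_pack,
                        sugar_g = p$sugar_g_per_pack,
                        salt_g = p$salt_g_per_pack),
                  group = items$participant_id)
    colnames(agg) <- paste0(label, "_", colnames(agg))
    agg
  }
  agg <- cbind(totals(items$product_id, "baseline"),
               totals(final_id, "final"),
               totals(potential_id, "potential"))
  baskets_tab <- data.frame(participant_id = rownames(agg), agg,
                            row.names = NULL, stringsAsFactors = FALSE)
  baskets_tab$arm <- parts$arm[match(baskets_tab$participant_id,
                                     parts$participant_id)]
  baskets_tab <- baskets_tab[match(parts$participant_id,
                                   baskets_tab$participant_id), , drop = FALSE]
  rownames(baskets_tab) <- NULL

  parts$n_items <- as.integer(table(items$participant_id)[parts$participant_id])
  off_tab <- rowsum(as.integer(!items$on_list), items$participant_id)
  parts$n_off_list <- as.integer(off_tab[match(parts$participant_id,
                                               rownames(off_tab)), 1L])
  parts$n_offers <- unname(n_offers)
  n_acc <- stats::setNames(rep(0L, nrow(parts)), parts$participant_id)
  acc_tab <- table(offers$participant_id[offers$accepted])
  n_acc[names(acc_tab)] <- as.integer(acc_tab)
  parts$n_accepted <- unname(n_acc)

  rownames(offers) <- NULL
  dataset <- new_trial_data(parts, offers, baskets_tab, catalog = cat,
                            seed = seed)
  apply_exclusions(dataset, rules)
}

#' Write the trial tables to a directory of CSV files
#'
#' Emits `participants.csv`, `offers.csv`, `baskets.csv` and
#' `exclusions.csv`.
#'
#' @param dataset A `trial_data` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  w(dataset$participants, "participants.csv")
  w(dataset$offers, "offers.csv")
  w(dataset$baskets, "baskets.csv")
  if (!is.null(dataset$exclusions)) w(dataset$exclusions, "exclusions.csv")
  invisible(dir)
}

#' Read trial tables written by [write_trial_dataset()]
#'
#' @param dir Directory holding the CSV tables.
#' @return A `trial_data` object.
#' @export
read_trial_dataset <- function(dir) {
  r <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) fail("missing trial table: %s", path)
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  excl <- file.path(dir, "exclusions.csv")
  new_trial_data(r("participants.csv"), r("offers.csv"), r("baskets.csv"),
                 exclusions = if (file.exists(excl)) r("exclusions.csv"))
}

#' Rebuild the trial's offer/participant/basket margins from printed counts
#'
#' Constructs a `trial_data` fixture whose margins equal the published
#' totals: 741/740/812 offers by frame with 106/85/107 accepted; 234/238/241
#' included participants of whom 78/58/66 accepted at least one offer; 726
#' one-alternative and 1516 two-alternative offers; and basket baselines
#' with mean 3622.85 kcal (SD 747.80), a constant 494.97 kcal potential
#' reduction per basket, and per-offer deltas averaging -9.69 kcal observed
#' and -92.93 kcal potential. The within-participant placement of accepted
#' offers is not published; it is distributed deterministically
#' (round-robin) so that every accepting participant holds at least one
#' accepted offer. The observed accounting identity (final = baseline + sum
#' of observed deltas) holds; the published basket-level and offer-level
#' *potential* figures are mutually inconsistent, so each is reproduced at
#' its own level.
#'
#' @return A `trial_data` object (no catalog attached).
#' @export
build_paper_counts_fixture <- function() {
  arms <- frame_levels
  n_part <- c(health = 234L, cost = 238L, social_norm = 241L)
  n_offers <- c(health = 741L, cost = 740L, social_norm = 812L)
  n_accepted <- c(health = 106L, cost = 85L, social_norm = 107L)
  n_accepters <- c(health = 78L, cost = 58L, social_norm = 66L)

  spread_counts <- function(total, n) {
    base <- total %/% n
    extra <- total %% n
    rep(c(base + 1L, base), c(extra, n - extra))
  }

  part_list <- list()
  offer_list <- list()
  for (a in arms) {
    P <- n_part[[a]]
    ids <- sprintf("F_%s_%03d", a, seq_len(P))
    per_offers <- spread_counts(n_offers[[a]], P)
    # accepted offers live on the first `n_accepters` participants, each >= 1
    per_accepted <- integer(P)
    per_accepted[seq_len(n_accepters[[a]])] <-
      spread_counts(n_accepted[[a]], n_accepters[[a]])
    stopifnot(all(per_accepted <= per_offers))
    part_list[[a]] <- data.frame(
      participant_id = ids, arm = a, included = TRUE,
      n_items = 12L, n_off_list = 0L,
      n_offers = per_offers, n_accepted = per_accepted,
      exclusion_reason = NA_character_, stringsAsFactors = FALSE
    )
    offer_list[[a]] <- data.frame(
      participant_id = rep(ids, per_offers),
      frame = a,
      accepted = unlist(lapply(seq_len(P), function(i) {
        rep(c(TRUE, FALSE), c(per_accepted[i], per_offers[i] - per_accepted[i]))
      })),
      n_offers_for_participant = rep(per_offers, per_offers),
      stringsAsFactors = FALSE
    )
  }
  participants <- do.call(rbind, part_list)
  offers <- do.call(rbind, offer_list)
  rownames(participants) <- rownames(offers) <- NULL
  offers$offer_id <- sprintf("offer_%04d", seq_len(nrow(offers)))
  # 1516 of 2262 offers showed two alternatives
  offers$n_alternatives <- rep(c(2L, 1L), c(1516L, nrow(offers) - 1516L))
  offers$decision <- ifelse(offers$accepted, "accept_first", "keep")
  # per-offer deltas reproducing the printed means exactly:
  # observed: total = -9.69 * 2262 kcal, carried by the 292 accepted offers
  total_observed <- -9.69 * sum(n_offers)
  offers$observed_delta_kcal <- ifelse(offers$accepted,
                                       total_observed / sum(n_accepted), 0)
  offers$potential_delta_kcal <- -92.93
  offers$original_kcal <- 300 + 25 * sin(seq_len(nrow(offers)))

  # baskets: symmetric spread around the printed baseline mean; the step is
  # chosen so the SD matches the printed 747.80
  n <- nrow(participants)
  step <- 747.80 / sqrt(n * (n + 1) / 12) # sample SD of the spread = 747.80
  baseline <- 3622.85 + step * (seq_len(n) - (n + 1) / 2)
  obs_by_part <- rowsum(offers$observed_delta_kcal, offers$participant_id)
  obs <- obs_by_part[match(participants$participant_id, rownames(obs_by_part)), 1L]
  baskets <- data.frame(
    participant_id = participants$participant_id,
    arm = participants$arm,
    baseline_kcal = baseline,
    final_kcal = baseline + obs,
    potential_kcal = baseline - 494.97,
    stringsAsFactors = FALSE
  )
  new_trial_data(participants, offers, baskets)
}
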