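# The four-criteria eligibility filter, offer construction, decisions.

test_that("is_eligible applies each criterion with the documented boundaries", {
  cat <- fixture_catalog()
  g <- function(id) get_products_for_test(cat, id)
  orig <- g("bisc_orig")
  # all four criteria hold: same category, weight 310/300, 1.10 in [0.96, 1.20), reduction 30
  expect_true(is_eligible(orig, g("bisc_alt1")))
  # criterion (iii) is strict: equal price is not "cost less"
  expect_false(is_eligible(orig, g("bisc_same_price")))
  # criterion (i): same numbers, different shelf category
  expect_false(is_eligible(orig, g("crisps_low")))
  # criterion (iv): reduction 15 < 23.9006 kcal/100 g
  expect_false(is_eligible(orig, g("bisc_small_red")))
  # identical product is an argument error, not FALSE
  expect_error(is_eligible(orig, orig), "same product")
})

test_that("price and weight boundaries behave as documented", {
  crit <- swap_criteria()
  mk <- function(id, price, weight, dens, cat = "c") {
    data.frame(product_id = id, name = id, shelf_category = cat,
               price_gbp = price, pack_weight_g = weight,
               energy_kcal_per_100g = dens, sat_fat_g_per_pack = 0,
               sugar_g_per_pack = 0, salt_g_per_pack = 0)
  }
  o <- mk("o", 1.00, 100, 300)
  # price exactly at the 20% floor is allowed (inclusive lower bound)
  expect_true(is_eligible(o, mk("a", 0.80, 100, 270), crit))
  expect_false(is_eligible(o, mk("b", 0.799, 100, 270), crit))
  # weight exactly at 90% and 110% is allowed
  expect_true(is_eligible(o, mk("c", 0.9, 90, 270), crit))
  expect_true(is_eligible(o, mk("d", 0.9, 110, 270), crit))
  expect_false(is_eligible(o, mk("e", 0.9, 89.9, 270), crit))
  # density reduction exactly at the threshold is allowed (a representable
  # threshold avoids testing floating-point round-off instead of the rule)
  crit24 <- swap_criteria(min_density_reduction = 24)
  expect_true(is_eligible(o, mk("f", 0.9, 100, 276), crit24))
  expect_false(is_eligible(o, mk("g", 0.9, 100, 276.5), crit24))
})

test_that("eligible_alternatives matches brute force and ranks as documented", {
  cat <- fixture_catalog()
  alts <- eligible_alternatives("bisc_orig", cat)
  expect_identical(alts$product_id,
                   brute_force_alternatives("bisc_orig", cat$products))
  # reductions 40 (alt2), 35 (alt3), 30 (alt1): descending
  expect_identical(alts$product_id, c("bisc_alt2", "bisc_alt3", "bisc_alt1"))
  # no candidates at all
  expect_equal(nrow(eligible_alternatives("soup_a", cat)), 0L)
  expect_error(eligible_alternatives("nope", cat), "not in catalog")
})

test_that("eligible_alternatives equals brute force on random catalogs", {
  for (seed in 1:60) {
    prods <- random_products(seed)
    cat <- catalog(prods)
    for (pid in prods$product_id) {
      got <- eligible_alternatives(pid, cat)$product_id
      expect_identical(got, brute_force_alternatives(pid, prods),
                       info = sprintf("seed %d, product %s", seed, pid))
    }
  }
})

test_that("tightening the filter never admits new candidates", {
  base <- swap_criteria()
  tighter_price <- swap_criteria(max_price_reduction_frac = 0.10)
  wider_density <- swap_criteria(min_density_reduction = 50)
  for (seed in c(2, 11, 23)) {
    cat <- catalog(random_products(seed))
    for (pid in cat$products$product_id) {
      n0 <- nrow(eligible_alternatives(pid, cat, base))
      expect_lte(nrow(eligible_alternatives(pid, cat, tighter_price)), n0)
      expect_lte(nrow(eligible_alternatives(pid, cat, wider_density)), n0)
    }
  }
})

test_that("build_offer shows one alternative when one qualifies, else the top two", {
  cat <- fixture_catalog()
  # cheese_a has exactly one eligible alternative
  off1 <- build_offer(list(slot = 1L, product_id = "cheese_a"), cat)
  expect_length(off1$alternative_ids, 1L)
  expect_identical(off1$alternative_ids, "cheese_b")
  # bisc_orig has three; the two highest-ranked are shown
  off3 <- build_offer(list(slot = 2L, product_id = "bisc_orig"), cat)
  expect_identical(off3$alternative_ids, c("bisc_alt2", "bisc_alt3"))
  expect_identical(off3$decision, "keep")
  # soup_a has none
  expect_null(build_offer(list(slot = 3L, product_id = "soup_a"), cat))
})

test_that("checkout offers: per-item rule, basket order, duplicates independent", {
  cat <- fixture_catalog()
  b <- fixture_basket()
  offers <- offer_swaps_at_checkout(b, cat, frame = "cost")
  # brute-force expectation: slots whose product has >= 1 eligible alternative
  expected_slots <- b$slot[vapply(b$product_id, function(id) {
    length(brute_force_alternatives(id, cat$products)) > 0
  }, logical(1L))]
  expect_equal(vapply(offers, `[[`, numeric(1L), "slot"), expected_slots)
  expect_lte(length(offers), nrow(b))
  # the duplicated original generates two independent offers
  orig_ids <- vapply(offers, `[[`, character(1L), "original_id")
  expect_equal(sum(orig_ids == "bisc_orig"), 2L)
  expect_true(all(vapply(offers, `[[`, character(1L), "frame") == "cost"))
})

test_that("apply_decision records deltas and swaps the basket item", {
  cat <- fixture_catalog()
  b <- fixture_basket()
  offers <- offer_swaps_at_checkout(b, cat)
  off <- offers[[1L]] # bisc_orig in slot 1, alternatives alt2, alt3

  kept <- apply_decision(off, b, cat)
  expect_equal(kept$offer$observed_delta_kcal, 0)
  expect_identical(kept$basket$product_id[1L], "bisc_orig")

  off$decision <- "accept_first"
  acc <- apply_decision(off, b, cat)
  # pack energies: original 480*3 = 1440, bisc_alt2 440*3 = 1320
  expect_equal(acc$offer$observed_delta_kcal, 1320 - 1440)
  expect_equal(acc$offer$potential_delta_kcal, 1320 - 1440)
  expect_identical(acc$basket$product_id[1L], "bisc_alt2")

  off$decision <- "accept_second"
  acc2 <- apply_decision(off, b, cat)
  expect_equal(acc2$offer$observed_delta_kcal, 445 * 2.95 - 1440)

  one_alt <- offers[[which(vapply(offers, function(o)
    length(o$alternative_ids), integer(1L)) == 1L)[1L]]]
  one_alt$decision <- "accept_second"
  expect_error(apply_decision(one_alt, b, cat), "single alternative")
})

test_that("the worked accept example gives -45 kcal", {
  cat <- fixture_catalog()
  b <- basket("P1", data.frame(slot = 1L, product_id = "bisc_orig",
                               on_list = TRUE))
  # force the offer to show only the 450 kcal/100 g alternative
  off <- build_offer(list(slot = 1L, product_id = "bisc_orig"), cat,
                     swap_criteria(weight_ratio_min = 1.0,
                                   max_price_reduction_frac = 0.09))
  expect_identical(off$alternative_ids, "bisc_alt1")
  off$decision <- "accept_first"
  res <- apply_decision(off, b, cat)
  expect_equal(res$offer$observed_delta_kcal, -45) # 1395 - 1440
})

test_that("swap_criteria validates its invariants", {
  expect_error(swap_criteria(weight_ratio_min = 1.2), "weight ratio")
  expect_error(swap_criteria(max_price_reduction_frac = 1), "\\[0, 1\\)")
  expect_error(swap_criteria(min_density_reduction = 0), "positive")
})
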