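# Hand-built fixture catalog and baskets used across the tests. The
# sweet_biscuits category is constructed around the canonical worked example:
# a 300 g, 1.20 GBP, 480 kcal/100 g original with candidates probing each of
# the four eligibility criteria.

fixture_catalog <- function() {
  p <- data.frame(
    product_id = c("bisc_orig", "bisc_alt1", "bisc_alt2", "bisc_alt3",
                   "bisc_same_price", "bisc_small_red",
                   "crisps_low", "soup_a", "cheese_a", "cheese_b"),
    name = c("digestive originals", "digestive light", "rich tea light",
             "oat thins light", "digestive value", "digestive reduced",
             "salted crisps", "tomato soup", "mature cheddar", "lighter cheddar"),
    shelf_category = c(rep("sweet_biscuits", 6L), "crisps", "fresh_soup",
                       "cheddar_cheese", "cheddar_cheese"),
    price_gbp = c(1.20, 1.10, 1.00, 1.15, 1.20, 1.10, 1.10, 1.50, 2.50, 2.30),
    pack_weight_g = c(300, 310, 300, 295, 305, 300, 300, 400, 250, 240),
    energy_kcal_per_100g = c(480, 450, 440, 445, 450, 465, 450, 80, 410, 380),
    sat_fat_g_per_pack = c(10, 8, 7, 7.5, 9, 9.5, 6, 2, 20, 15),
    sugar_g_per_pack = c(30, 26, 24, 25, 28, 29, 2, 8, 1, 1),
    salt_g_per_pack = c(1, 0.9, 0.8, 0.85, 1, 0.95, 1.5, 2, 1.8, 1.6),
    stringsAsFactors = FALSE
  )
  catalog(p)
}

get_products_for_test <- function(cat, id) {
  cat$products[cat$products$product_id == id, ]
}

# 12-slot basket over the fixture catalog; several slots carry products with
# eligible alternatives (including a duplicated original)
fixture_basket <- function(pid = "P0001") {
  basket(pid, data.frame(
    slot = 1:12,
    product_id = c("bisc_orig", "cheese_a", "soup_a", "crisps_low",
                   "bisc_alt1", "cheese_b", "soup_a", "bisc_orig",
                   "bisc_small_red", "bisc_same_price", "bisc_alt2",
                   "cheese_a"),
    on_list = rep(TRUE, 12L),
    stringsAsFactors = FALSE
  ))
}
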