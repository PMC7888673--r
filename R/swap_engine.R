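# The automated lower-energy alternative-finding algorithm: a candidate
# product is an eligible swap for an original choice when it
#   (i)   sits in the same shelf category,
#   (ii)  weighs between 90% and 110% of the original (inclusive),
#   (iii) costs less than the original, but by at most 20% (lower bound
#         inclusive, upper bound strict: it must cost *less*),
#   (iv)  is less energy dense by at least 100 kJ (23.9006 kcal) per 100 g.
# Offers present the top one or two eligible candidates at checkout.

#' Swap-eligibility criteria
#'
#' Thresholds of the alternative-finding algorithm. Boundary conventions:
#' the weight-ratio bounds and the density-reduction threshold are
#' inclusive; the price must be strictly lower than the original but no more
#' than `max_price_reduction_frac` below it (lower bound inclusive).
#'
#' @param weight_ratio_min,weight_ratio_max Allowed candidate/original pack
#'   weight ratio (defaults 0.90 and 1.10).
#' @param max_price_reduction_frac Largest allowed fractional price
#'   reduction (default 0.20).
#' @param min_density_reduction Minimum reduction in energy density,
#'   kcal/100 g. The default is the exact conversion of 100 kJ/100 g,
#'   100/4.184 = 23.9006, rather than the rounded 24.
#' @param require_same_category Require candidate and original to share a
#'   shelf category (default `TRUE`).
#' @param max_alternatives_shown Number of top-ranked alternatives shown in
#'   an offer (default 2).
#' @return An object of class `swap_criteria`.
#' @export
swap_criteria <- function(weight_ratio_min = 0.90,
                          weight_ratio_max = 1.10,
                          max_price_reduction_frac = 0.20,
                          min_density_reduction = kj_to_kcal(100),
                          require_same_category = TRUE,
                          max_alternatives_shown = 2L) {
  if (!(is_number(weight_ratio_min) && is_number(weight_ratio_max) &&
        weight_ratio_min > 0 && weight_ratio_min <= 1 &&
        weight_ratio_max >= 1)) {
    fail("weight ratio bounds must satisfy 0 < min <= 1 <= max")
  }
  if (!is_number(max_price_reduction_frac) ||
      max_price_reduction_frac < 0 || max_price_reduction_frac >= 1) {
    fail("max_price_reduction_frac must be in [0, 1)")
  }
  if (!is_number(min_density_reduction) || min_density_reduction <= 0) {
    fail("min_density_reduction must be positive")
  }
  if (!is_flag(require_same_category)) fail("require_same_category must be a flag")
  if (!is_count(max_alternatives_shown)) fail("max_alternatives_shown must be a count")
  structure(list(
    weight_ratio_min = weight_ratio_min,
    weight_ratio_max = weight_ratio_max,
    max_price_reduction_frac = max_price_reduction_frac,
    min_density_reduction = min_density_reduction,
    require_same_category = require_same_category,
    max_alternatives_shown = as.integer(max_alternatives_shown)
  ), class = "swap_criteria")
}

#' Is a candidate product an eligible swap for an original choice?
#'
#' @param original,candidate Single catalog rows (one-row data.frames).
#' @param criteria A [swap_criteria()] object.
#' @return `TRUE` iff all active criteria hold.
#' @export
is_eligible <- function(original, candidate, criteria = swap_criteria()) {
  if (identical(original$product_id, candidate$product_id)) {
    fail("candidate and original are the same product: %s", original$product_id)
  }
  ratio <- candidate$pack_weight_g / original$pack_weight_g
  reduction <- original$energy_kcal_per_100g - candidate$energy_kcal_per_100g
  (!criteria$require_same_category ||
     candidate$shelf_category == original$shelf_category) &&
    ratio >= criteria$weight_ratio_min &&
    ratio <= criteria$weight_ratio_max &&
    candidate$price_gbp < original$price_gbp &&
    candidate$price_gbp >= (1 - criteria$max_price_reduction_frac) * original$price_gbp &&
    reduction >= criteria$min_density_reduction
}

# Vectorised filter + ranking used by all offer construction. `original` is a
# one-row catalog slice. Returns a data.frame of eligible products ordered by
# descending density reduction, then ascending price, then product_id.
rank_alternatives <- function(original, cat, criteria) {
  p <- cat$products
  ratio <- p$pack_weight_g / original$pack_weight_g
  reduction <- original$energy_kcal_per_100g - p$energy_kcal_per_100g
  keep <- p$product_id != original$product_id &
    (!criteria$require_same_category | p$shelf_category == original$shelf_category) &
    ratio >= criteria$weight_ratio_min &
    ratio <= criteria$weight_ratio_max &
    p$price_gbp < original$price_gbp &
    p$price_gbp >= (1 - criteria$max_price_reduction_frac) * original$price_gbp &
    reduction >= criteria$min_density_reduction
  out <- p[keep, , drop = FALSE]
  out <- out[order(-reduction[keep], out$price_gbp, out$product_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' All eligible lower-energy alternatives for a product, ranked
#'
#' Applies the four eligibility criteria to every other catalog product and
#' ranks survivors by descending energy-density reduction, breaking ties by
#' ascending price and then product id (a deterministic, auditable
#' convention; the selection rule among multiple qualifying candidates is a
#' package choice).
#'
#' @param original A product id or a one-row catalog slice; must be in the
#'   catalog.
#' @param cat A `swap_catalog`.
#' @param criteria A [swap_criteria()] object.
#' @return A (possibly empty) data.frame of eligible products in rank order.
#' @export
eligible_alternatives <- function(original, cat, criteria = swap_criteria()) {
  if (is.character(original)) original <- get_products(cat, original)
  if (!original$product_id %in% cat$products$product_id) {
    fail("product id(s) not in catalog: %s", original$product_id)
  }
  rank_alternatives(original, cat, criteria)
}

new_swap_offer <- function(offer_id, participant_id, slot, original_id,
                           alternative_ids, frame,
                           decision = "keep") {
  structure(list(
    offer_id = offer_id,
    participant_id = participant_id,
    slot = slot,
    original_id = original_id,
    alternative_ids = alternative_ids,
    frame = frame,
    decision = decision,
    observed_delta_kcal = NA_real_,
    potential_delta_kcal = NA_real_
  ), class = "swap_offer")
}

#' @exportS3Method print swap_offer
print.swap_offer <- function(x, ...) {
  cat(sprintf("<swap_offer %s> %s: %s -> [%s] (%s frame, decision: %s)\n",
              x$offer_id, x$participant_id, x$original_id,
              paste(x$alternative_ids, collapse = ", "), x$frame, x$decision))
  invisible(x)
}

#' Build a swap offer for one basket item
#'
#' Returns `NULL` when no eligible alternative exists; otherwise an offer
#' showing the single qualifying alternative, or the two top-ranked ones
#' when two or more qualify. The decision is initialised to `"keep"`.
#'
#' @param item One basket row (with `slot` and `product_id`).
#' @param cat A `swap_catalog`.
#' @param criteria A [swap_criteria()] object.
#' @param frame Message frame shown with the offer: `"health"`, `"cost"` or
#'   `"social_norm"`.
#' @param participant_id,offer_id Identifiers carried on the offer.
#' @return A `swap_offer` or `NULL`.
#' @export
build_offer <- function(item, cat, criteria = swap_criteria(),
                        frame = "health", participant_id = NA_character_,
                        offer_id = NA_character_) {
  frame <- match.arg(frame, c("health", "cost", "social_norm"))
  alts <- eligible_alternatives(item$product_id, cat, criteria)
  if (nrow(alts) == 0L) return(NULL)
  shown <- utils::head(alts$product_id, criteria$max_alternatives_shown)
  new_swap_offer(offer_id, participant_id, item$slot, item$product_id,
                 shown, frame)
}

#' Offer swaps for every swap-relevant item at checkout
#'
#' One offer per basket item that has at least one eligible alternative, in
#' basket (slot) order. Offers are evaluated once against the basket as it
#' stands at checkout; accepting one offer never triggers re-evaluation of
#' other items, and the swapped-in product never generates a new offer.
#' Every emitted alternative is self-checked against [is_eligible()].
#'
#' @param bsk A `swap_basket`.
#' @param cat A `swap_catalog`.
#' @param criteria A [swap_criteria()] object.
#' @param frame Message frame for all of this shopper's offers.
#' @return List of `swap_offer` objects (possibly empty; a shopper with no
#'   swap-relevant items is later excluded by the trial's rule (v)).
#' @export
offer_swaps_at_checkout <- function(bsk, cat, criteria = swap_criteria(),
                                    frame = "health") {
  pid <- attr(bsk, "participant_id")
  offers <- list()
  for (i in seq_len(nrow(bsk))) {
    off <- build_offer(bsk[i, ], cat, criteria, frame, participant_id = pid)
    if (is.null(off)) next
    off$offer_id <- sprintf("%s_o%d", pid, length(offers) + 1L)
    orig <- get_products(cat, off$original_id)
    for (aid in off$alternative_ids) {
      if (!is_eligible(orig, get_products(cat, aid), criteria)) {
        fail("internal: emitted alternative %s fails eligibility against %s",
             aid, off$original_id)
      }
    }
    offers[[length(offers) + 1L]] <- off
  }
  offers
}

#' Apply a shopper's decision to an offer
#'
#' Records the observed energy change (chosen pack kcal minus original pack
#' kcal; 0 when the offer is kept) and the potential change (top-ranked
#' alternative minus original, regardless of the decision), and replaces the
#' basket item when the offer was accepted.
#'
#' @param offer A `swap_offer` with `decision` set to `"keep"`,
#'   `"accept_first"` or `"accept_second"`.
#' @param bsk The shopper's `swap_basket`.
#' @param cat The resolving `swap_catalog`.
#' @return A list with the updated `basket` and the `offer` with both deltas
#'   filled in.
#' @export
apply_decision <- function(offer, bsk, cat) {
  decision <- match.arg(offer$decision, c("keep", "accept_first", "accept_second"))
  if (decision == "accept_second" && length(offer$alternative_ids) < 2L) {
    fail("decision accept_second but offer %s shows a single alternative",
         offer$offer_id)
  }
  orig_kcal <- energy_per_pack(get_products(cat, offer$original_id))
  top_kcal <- energy_per_pack(get_products(cat, offer$alternative_ids[1L]))
  offer$potential_delta_kcal <- top_kcal - orig_kcal
  if (decision == "keep") {
    offer$observed_delta_kcal <- 0
  } else {
    chosen <- offer$alternative_ids[if (decision == "accept_first") 1L else 2L]
    offer$observed_delta_kcal <-
      energy_per_pack(get_products(cat, chosen)) - orig_kcal
    bsk$product_id[bsk$slot == offer$slot] <- chosen
  }
  list(basket = bsk, offer = offer)
}
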