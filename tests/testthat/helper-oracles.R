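# Independent oracles, deliberately written as plain loops / closed forms so
# they share no code with the package implementation.

# Brute-force eligibility filter: explicit per-candidate checks of the four
# criteria, then the documented ordering (descending density reduction,
# ascending price, ascending product_id).
brute_force_alternatives <- function(original_id, products,
                                     wmin = 0.90, wmax = 1.10,
                                     max_cut = 0.20, min_red = 100 / 4.184) {
  ids <- products$product_id
  cats <- products$shelf_category
  prices <- products$price_gbp
  weights <- products$pack_weight_g
  dens <- products$energy_kcal_per_100g
  oi <- which(ids == original_id)
  keep <- character(0)
  red <- numeric(0)
  price <- numeric(0)
  for (i in seq_along(ids)) {
    if (i == oi) next
    if (cats[i] != cats[oi]) next
    r <- weights[i] / weights[oi]
    if (r < wmin || r > wmax) next
    if (!(prices[i] < prices[oi])) next
    if (prices[i] < (1 - max_cut) * prices[oi]) next
    d <- dens[oi] - dens[i]
    if (d < min_red) next
    keep <- c(keep, ids[i])
    red <- c(red, d)
    price <- c(price, prices[i])
  }
  keep[order(-red, price, keep)]
}

# random small catalog for property testing; densities/weights/prices chosen
# so that all four criteria bind with appreciable probability
random_products <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(5:50, 1L)
  data.frame(
    product_id = sprintf("r%03d", seq_len(n)),
    name = sprintf("random product %d", seq_len(n)),
    shelf_category = sample(c("cat_a", "cat_b", "cat_c"), n, replace = TRUE),
    price_gbp = round(runif(n, 0.5, 3.0), 2),
    pack_weight_g = round(runif(n, 80, 160), 1),
    energy_kcal_per_100g = round(runif(n, 100, 400), 1),
    sat_fat_g_per_pack = round(runif(n, 0, 10), 2),
    sugar_g_per_pack = round(runif(n, 0, 30), 2),
    salt_g_per_pack = round(runif(n, 0, 2), 2),
    stringsAsFactors = FALSE
  )
}

# two-parameter logistic MLE by nested grid search over the log-likelihood
grid_mle_logit <- function(y, x, span = 5, steps = 3L, grid_n = 61L) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log(1 + exp(eta)))
  }
  centre <- c(0, 0)
  width <- span
  for (s in seq_len(steps)) {
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = grid_n)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = grid_n)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    centre <- c(b0s[best[1]], b1s[best[2]])
    width <- width * 2.5 / grid_n * 2 # a few grid cells around the optimum
  }
  centre
}
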