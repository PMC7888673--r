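# Product catalog and basket data model: validation, energy/nutrient
# accounting, and CSV I/O.

catalog_columns <- c(
  "product_id", "name", "shelf_category", "price_gbp", "pack_weight_g",
  "energy_kcal_per_100g", "sat_fat_g_per_pack", "sugar_g_per_pack",
  "salt_g_per_pack"
)

basket_columns <- c("participant_id", "slot", "product_id", "on_list")

#' Construct a product catalog
#'
#' A catalog is a validated table of products plus the taxonomy of shelf
#' categories they may come from. Shelf category is the grouping the swap
#' algorithm uses for its "same product category" criterion.
#'
#' @param products A data.frame with columns `product_id`, `name`,
#'   `shelf_category`, `price_gbp` (> 0), `pack_weight_g` (> 0),
#'   `energy_kcal_per_100g` (>= 0), and per-pack `sat_fat_g_per_pack`,
#'   `sugar_g_per_pack`, `salt_g_per_pack` (>= 0).
#' @param taxonomy Character vector of allowed shelf categories. Defaults to
#'   the categories present in `products`.
#' @return An object of class `swap_catalog`: a list with elements `products`
#'   and `taxonomy`.
#' @export
catalog <- function(products, taxonomy = sort(unique(products$shelf_category))) {
  stopifnot(is.data.frame(products))
  missing_cols <- setdiff(catalog_columns, names(products))
  if (length(missing_cols)) {
    fail("catalog is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  extra_cols <- setdiff(names(products), catalog_columns)
  if (length(extra_cols)) {
    fail("catalog has unexpected column(s): %s", paste(extra_cols, collapse = ", "))
  }
  if (nrow(products) == 0L) fail("catalog must contain at least one product")
  products <- products[, catalog_columns]
  num_cols <- setdiff(catalog_columns, c("product_id", "name", "shelf_category"))
  for (col in num_cols) {
    if (!is.numeric(products[[col]])) fail("column %s must be numeric", col)
    products[[col]] <- as.double(products[[col]])
  }
  bad <- which(!(products$price_gbp > 0) | !(products$pack_weight_g > 0))
  if (length(bad)) {
    fail("non-positive price or pack weight in row(s) %s",
         paste(bad, collapse = ", "))
  }
  bad <- which(products$energy_kcal_per_100g < 0 |
                 products$sat_fat_g_per_pack < 0 |
                 products$sugar_g_per_pack < 0 |
                 products$salt_g_per_pack < 0)
  if (length(bad)) {
    fail("negative energy density or nutrient content in row(s) %s",
         paste(bad, collapse = ", "))
  }
  dup <- products$product_id[duplicated(products$product_id)]
  if (length(dup)) {
    fail("duplicated product_id: %s", paste(unique(dup), collapse = ", "))
  }
  off <- setdiff(products$shelf_category, taxonomy)
  if (length(off)) {
    fail("shelf_category not in taxonomy: %s", paste(off, collapse = ", "))
  }
  structure(list(products = products, taxonomy = taxonomy),
            class = "swap_catalog")
}

#' @exportS3Method print swap_catalog
print.swap_catalog <- function(x, ...) {
  cat(sprintf("<swap_catalog> %d products in %d shelf categories\n",
              nrow(x$products), length(x$taxonomy)))
  invisible(x)
}

#' Read a product catalog from CSV
#'
#' Expects UTF-8, comma-separated values with a header row and "." as the
#' decimal mark; columns as documented in [catalog()].
#'
#' @param path Path to the CSV file.
#' @return A `swap_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) fail("catalog file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  catalog(df)
}

#' Write a product catalog to CSV
#'
#' @param cat A `swap_catalog`.
#' @param path Output path.
#' @return `path`, invisibly. Reading the file back with [read_catalog()]
#'   reproduces the catalog field by field.
#' @export
write_catalog <- function(cat, path) {
  stopifnot(inherits(cat, "swap_catalog"))
  utils::write.csv(cat$products, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Look up product rows by id, preserving the order of `ids`.
get_products <- function(cat, ids) {
  idx <- match(ids, cat$products$product_id)
  if (anyNA(idx)) {
    fail("product id(s) not in catalog: %s",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  }
  cat$products[idx, , drop = FALSE]
}

#' Energy content of one pack of a product
#'
#' @param product One or more catalog rows (a data.frame with
#'   `energy_kcal_per_100g` and `pack_weight_g`).
#' @return kcal per pack: energy density times pack weight / 100. Vectorised
#'   over rows.
#' @export
#' @examples
#' p <- data.frame(energy_kcal_per_100g = 480, pack_weight_g = 300)
#' energy_per_pack(p) # 1440
energy_per_pack <- function(product) {
  product$energy_kcal_per_100g * product$pack_weight_g / 100
}

#' Construct a shopping basket
#'
#' One unit is purchased per basket slot; the task uses a 12-slot shopping
#' list, so slot indices must lie in 1..12.
#'
#' @param participant_id Id of the shopper.
#' @param items data.frame with columns `slot` (integer 1-12, unique),
#'   `product_id`, and `on_list` (logical: was the item on the pre-set list).
#' @return An object of class `swap_basket` (a data.frame with a
#'   `participant_id` attribute).
#' @export
basket <- function(participant_id, items) {
  stopifnot(is.data.frame(items))
  missing_cols <- setdiff(c("slot", "product_id", "on_list"), names(items))
  if (length(missing_cols)) {
    fail("basket items missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(items)) {
    if (any(items$slot < 1 | items$slot > 12 | items$slot != round(items$slot))) {
      fail("basket slots must be integers in 1..12")
    }
    if (anyDuplicated(items$slot)) fail("basket slots must be unique")
  }
  items <- items[order(items$slot), c("slot", "product_id", "on_list")]
  rownames(items) <- NULL
  structure(items, participant_id = as.character(participant_id),
            class = c("swap_basket", "data.frame"))
}

#' Read baskets from CSV
#'
#' Expects columns `participant_id,slot,product_id,on_list`; returns one
#' basket per participant.
#'
#' @param path Path to the CSV file.
#' @return Named list of `swap_basket` objects.
#' @export
read_baskets <- function(path) {
  if (!file.exists(path)) fail("basket file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(basket_columns, names(df))
  if (length(missing_cols)) {
    fail("basket file missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df$on_list <- as.logical(df$on_list)
  out <- lapply(split(df, df$participant_id), function(d) {
    basket(d$participant_id[1L], d[, c("slot", "product_id", "on_list")])
  })
  out[unique(df$participant_id)]
}

#' Basket totals: energy and nutrients
#'
#' Sums pack energy (kcal) and per-pack saturated fat, sugar and salt (g)
#' over all items in a basket, one unit per slot.
#'
#' @param bsk A `swap_basket`.
#' @param cat The `swap_catalog` resolving the basket's product ids.
#' @return A one-row data.frame with columns `kcal`, `sat_fat_g`, `sugar_g`,
#'   `salt_g`.
#' @export
basket_totals <- function(bsk, cat) {
  if (nrow(bsk) == 0L) {
    return(data.frame(kcal = 0, sat_fat_g = 0, sugar_g = 0, salt_g = 0))
  }
  p <- get_products(cat, bsk$product_id)
  data.frame(
    kcal = sum(energy_per_pack(p)),
    sat_fat_g = sum(p$sat_fat_g_per_pack),
    sugar_g = sum(p$sugar_g_per_pack),
    salt_g = sum(p$salt_g_per_pack)
  )
}
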