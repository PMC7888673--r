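# Shared internal helpers: units, seed substreams, small validators.

#' Convert kilojoules to kilocalories
#'
#' The canonical energy unit throughout the package is kcal; the eligibility
#' threshold of the swap algorithm is stated in kJ per 100 g and converted at
#' 1 kcal = 4.184 kJ.
#'
#' @param kj Energy in kJ.
#' @return Energy in kcal.
#' @export
#' @examples
#' kj_to_kcal(100) # 23.9006..., the default density-reduction threshold
kj_to_kcal <- function(kj) kj / 4.184

#' Derive a reproducible substream seed from a master seed and a key
#'
#' Random draws tied to a participant (shopping, random intercepts) use a
#' substream seeded by a stable hash of the participant id combined with the
#' master seed, so that editing one part of a cohort does not reshuffle every
#' other participant's draws. The result is always a valid 32-bit seed.
#'
#' @param seed Master seed (integer).
#' @param key Character scalar identifying the substream.
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, key) {
  h <- 0
  for (cp in utf8ToInt(as.character(key))) {
    h <- (h * 131 + cp) %% 2147480009
  }
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629)
}

# stop() with a consistent, uncluttered error surface
fail <- function(...) stop(sprintf(...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) is_number(x) && x >= 1 && x == round(x)

is_prob <- function(x) is_number(x) && x >= 0 && x <= 1
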