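# Simulation-based power analysis for the two-proportion acceptance
# comparison (baseline vs framed arm), with optional SES moderation,
# clustered repeated offers, and a closed-form normal-approximation oracle
# for the uncorrelated one-offer limit.

#' Power-analysis design
#'
#' Defaults encode the trial's design assumptions: a jump in swap acceptance
#' from 25% in the health (baseline) arm to 35% in a framed arm, moderated
#' by +/- 12 percentage points between the lowest and highest SES quartile,
#' tested at alpha = 0.05. The simulation compares the baseline arm against
#' one framed arm (`n_per_arm` shoppers each).
#'
#' @param arms Number of arms in the trial (context only; the test contrasts
#'   two of them).
#' @param n_per_arm Shoppers per arm (default 300, i.e. 900 over 3 arms).
#' @param baseline_acceptance,target_acceptance Acceptance probabilities in
#'   the baseline and framed arm (defaults 0.25 and 0.35).
#' @param ses_moderation Probability offset of the framed-arm acceptance
#'   between the extreme SES quartiles (default 0.12, so the framed-arm
#'   probability runs from `target - 0.12` to `target + 0.12` across
#'   quartiles). Implemented as a linear-in-logit interaction calibrated so
#'   the extreme-quartile probability gap equals `2 * ses_moderation` at the
#'   target.
#' @param offers_per_participant Either a single count (default 1) or a
#'   probability vector over 1, 2, 3, ... offers.
#' @param random_intercept_sd Participant-level log-odds SD (default 0; the
#'   within-shopper correlation of repeated offers).
#' @param alpha Two-sided significance level (default 0.05).
#' @param test `"proportion"` (unpooled two-sample z on participant-level
#'   acceptance proportions) or `"wald"` (offer-level logistic Wald test of
#'   the arm coefficient).
#' @return An object of class `power_design`.
#' @export
power_design <- function(arms = 3L, n_per_arm = 300L,
                         baseline_acceptance = 0.25,
                         target_acceptance = 0.35,
                         ses_moderation = 0.12,
                         offers_per_participant = 1L,
                         random_intercept_sd = 0,
                         alpha = 0.05,
                         test = c("proportion", "wald")) {
  test <- match.arg(test)
  if (!is_prob(baseline_acceptance) || baseline_acceptance <= 0 ||
      baseline_acceptance >= 1 ||
      !is_prob(target_acceptance) || target_acceptance <= 0 ||
      target_acceptance >= 1) {
    fail("acceptance probabilities must lie strictly inside (0, 1)")
  }
  if (!is_count(n_per_arm) || n_per_arm < 2) fail("n_per_arm must be >= 2")
  if (length(offers_per_participant) == 1L) {
    if (!is_count(offers_per_participant)) {
      fail("offers_per_participant must be a count or a probability vector")
    }
  } else if (abs(sum(offers_per_participant) - 1) > 1e-8 ||
             any(offers_per_participant < 0)) {
    fail("offers_per_participant probabilities must sum to 1")
  }
  if (!is_number(random_intercept_sd) || random_intercept_sd < 0) {
    fail("random_intercept_sd must be non-negative")
  }
  structure(list(arms = as.integer(arms), n_per_arm = as.integer(n_per_arm),
                 baseline_acceptance = baseline_acceptance,
                 target_acceptance = target_acceptance,
                 ses_moderation = ses_moderation,
                 offers_per_participant = offers_per_participant,
                 random_intercept_sd = random_intercept_sd,
                 alpha = alpha, test = test),
            class = "power_design")
}

#' Closed-form two-proportion power (normal approximation, unpooled)
#'
#' Power of the two-sided unpooled z-test comparing independent proportions
#' `p0` and `p1` with `n_per_arm` per group:
#' `pnorm(d/se - z) + pnorm(-d/se - z)` with `d = |p1 - p0|`,
#' `se = sqrt(p0(1-p0)/n + p1(1-p1)/n)` and `z = qnorm(1 - alpha/2)`.
#' Serves as the analytic oracle for the simulator in the uncorrelated
#' one-offer limit; under the null it returns `alpha`.
#'
#' @param p0,p1 The two proportions.
#' @param n_per_arm Sample size per group.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' analytic_power_two_prop(0.25, 0.35, 300) # ~0.77
analytic_power_two_prop <- function(p0, p1, n_per_arm, alpha = 0.05) {
  se <- sqrt(p0 * (1 - p0) / n_per_arm + p1 * (1 - p1) / n_per_arm)
  z <- stats::qnorm(1 - alpha / 2)
  d <- abs(p1 - p0)
  stats::pnorm(d / se - z) + stats::pnorm(-d / se - z)
}

draw_offer_counts <- function(n, spec) {
  if (length(spec) == 1L) {
    rep(as.integer(spec), n)
  } else {
    sample.int(length(spec), n, replace = TRUE, prob = spec)
  }
}

# one simulated comparison; returns TRUE when the null is rejected
simulate_one_rejection <- function(design) {
  n <- design$n_per_arm
  p0 <- design$baseline_acceptance
  p1 <- design$target_acceptance
  # framed-arm linear-in-logit SES moderation across quartiles 0..3
  q1 <- sample(0:3, n, replace = TRUE)
  if (design$ses_moderation > 0) {
    hi <- min(p1 + design$ses_moderation, 0.999)
    lo <- max(p1 - design$ses_moderation, 0.001)
    slope <- stats::qlogis(hi) - stats::qlogis(lo)
  } else {
    slope <- 0
  }
  ri0 <- stats::rnorm(n, 0, design$random_intercept_sd)
  ri1 <- stats::rnorm(n, 0, design$random_intercept_sd)
  eta0 <- stats::qlogis(p0) + ri0
  eta1 <- stats::qlogis(p1) + slope * (q1 / 3 - 0.5) + ri1
  m0 <- draw_offer_counts(n, design$offers_per_participant)
  m1 <- draw_offer_counts(n, design$offers_per_participant)
  y0 <- stats::rbinom(n, m0, stats::plogis(eta0))
  y1 <- stats::rbinom(n, m1, stats::plogis(eta1))
  if (design$test == "proportion") {
    prop_z_reject(y0 / m0, y1 / m1, design$alpha)
  } else {
    arm <- rep(c(0L, 1L), c(sum(m0), sum(m1)))
    acc <- c(unlist(mapply(function(y, m) rep(c(1L, 0L), c(y, m - y)),
                           y0, m0, SIMPLIFY = FALSE)),
             unlist(mapply(function(y, m) rep(c(1L, 0L), c(y, m - y)),
                           y1, m1, SIMPLIFY = FALSE)))
    fit <- stats::glm(acc ~ arm, family = stats::binomial())
    stats::coef(summary(fit))["arm", 4L] < design$alpha
  }
}

# unpooled two-sample z on participant-level acceptance proportions
prop_z_reject <- function(x0, x1, alpha) {
  n0 <- length(x0)
  n1 <- length(x1)
  se <- sqrt(stats::var(x0) * (n0 - 1) / n0 / n0 +
               stats::var(x1) * (n1 - 1) / n1 / n1)
  if (se == 0) return(FALSE)
  abs(mean(x1) - mean(x0)) / se > stats::qnorm(1 - alpha / 2)
}

#' Estimate power by simulation
#'
#' Simulates the design replicate by replicate (generate both arms, run the
#' chosen test at `alpha`, record the rejection) and returns the rejection
#' rate with its exact binomial 95% interval. In the uncorrelated one-offer
#' limit the whole simulation is vectorised. Deterministic under `seed`;
#' running different design points with the same seed gives common random
#' numbers for variance-reduced comparisons. Requesting a null effect
#' (`p0 == p1`) warns and proceeds, which measures the type-I error rate.
#'
#' @param design A [power_design()].
#' @param replicates Monte-Carlo replicates (>= 100 for reported results).
#' @param seed Integer seed.
#' @return An object of class `power_result`: `power`, `ci` (exact binomial
#'   95%), `replicates`, `seed`, `design`.
#' @export
estimate_power <- function(design = power_design(), replicates = 2000L,
                           seed = 1L) {
  if (!is_count(replicates)) fail("replicates must be a positive integer")
  if (design$baseline_acceptance == design$target_acceptance &&
      design$ses_moderation == 0) {
    warning("null design (p0 == p1): estimating the type-I error rate",
            call. = FALSE)
  }
  set.seed(seed)
  simple <- length(design$offers_per_participant) == 1L &&
    design$offers_per_participant == 1L &&
    design$random_intercept_sd == 0 && design$ses_moderation == 0 &&
    design$test == "proportion"
  if (simple) {
    n <- design$n_per_arm
    y0 <- stats::rbinom(replicates, n, design$baseline_acceptance)
    y1 <- stats::rbinom(replicates, n, design$target_acceptance)
    p0h <- y0 / n
    p1h <- y1 / n
    se <- sqrt(p0h * (1 - p0h) / n + p1h * (1 - p1h) / n)
    z <- stats::qnorm(1 - design$alpha / 2)
    rej <- se > 0 & abs(p1h - p0h) / se > z
  } else {
    rej <- vapply(seq_len(replicates), function(i) simulate_one_rejection(design),
                  logical(1L))
  }
  k <- sum(rej)
  ci <- as.numeric(stats::binom.test(k, replicates)$conf.int)
  structure(list(power = k / replicates, ci = ci, replicates = replicates,
                 seed = seed, design = design),
            class = "power_result")
}

#' @exportS3Method print power_result
print.power_result <- function(x, ...) {
  cat(sprintf("Estimated power: %.3f (95%% MC interval %.3f-%.3f, %d replicates)\n",
              x$power, x$ci[1L], x$ci[2L], x$replicates))
  invisible(x)
}

#' Smallest per-arm sample size on a grid achieving a target power
#'
#' Runs [estimate_power()] at every grid point with the same seed (common
#' random numbers) and returns the smallest per-arm n whose estimated power
#' meets the target, together with the whole power curve.
#'
#' @param design A [power_design()]; its `n_per_arm` is overridden by the
#'   grid.
#' @param target_power Required power (e.g. 0.80).
#' @param n_grid Ascending vector of per-arm sample sizes.
#' @param replicates Monte-Carlo replicates per grid point.
#' @param seed Integer seed, shared across grid points.
#' @return A list with `n_required` and the `curve` data.frame
#'   (`n_per_arm`, `power`, `ci_lo`, `ci_hi`).
#' @export
required_n <- function(design = power_design(), target_power = 0.80,
                       n_grid = c(100L, 200L, 300L, 450L, 600L),
                       replicates = 1000L, seed = 1L) {
  if (is.unsorted(n_grid, strictly = TRUE)) fail("n_grid must be sorted ascending")
  curve <- do.call(rbind, lapply(n_grid, function(n) {
    d <- design
    d$n_per_arm <- as.integer(n)
    r <- estimate_power(d, replicates, seed)
    data.frame(n_per_arm = n, power = r$power, ci_lo = r$ci[1L],
               ci_hi = r$ci[2L])
  }))
  hit <- which(curve$power >= target_power)
  if (!length(hit)) {
    fail("target power %.2f unattainable on the grid; maximum achieved %.3f at n = %d",
         target_power, max(curve$power), curve$n_per_arm[which.max(curve$power)])
  }
  list(n_required = curve$n_per_arm[hit[1L]], curve = curve)
}
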