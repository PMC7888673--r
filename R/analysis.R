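# The pre-registered analysis plan: descriptive accounting of offers and
# acceptance, logistic acceptance models (with an attempted participant
# random intercept and a logged fixed-effect fallback), multilevel per-swap
# energy-change models with a time dummy, basket-level paired tests and
# frame regressions, nutrient tests, balance checks, Bonferroni families.

#' Bonferroni-adjusted significance threshold
#'
#' @param base_alpha Family-wise level (default 0.05).
#' @param m Number of comparisons in the family (>= 1).
#' @return `base_alpha / m`. The trial reports thresholds to 3 decimals
#'   (0.05/2 = .025, 0.05/3 = .017); round the return value for display.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 2) # 0.025
#' round(bonferroni_alpha(0.05, 3), 3) # 0.017
bonferroni_alpha <- function(base_alpha = 0.05, m) {
  if (!is_count(m)) fail("m must be a positive integer")
  if (!is_prob(base_alpha)) fail("base_alpha must be a probability")
  base_alpha / m
}

new_swap_fit <- function(terms, model_label, family_alpha, converged = TRUE,
                         fallback = FALSE, fit = NULL) {
  rownames(terms) <- NULL
  structure(list(terms = terms, model_label = model_label,
                 family_alpha = family_alpha, converged = converged,
                 fallback = fallback, fit = fit),
            class = "swap_fit")
}

#' @exportS3Method print swap_fit
print.swap_fit <- function(x, digits = 2, ...) {
  cat(sprintf("<swap_fit> %s (family alpha = %.3f)%s\n", x$model_label,
              x$family_alpha,
              if (x$fallback) " [fixed-effect fallback: random-intercept fit did not converge]" else ""))
  tab <- x$terms
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$statistic <- round(tab$statistic, digits)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method summary swap_fit
summary.swap_fit <- function(object, ...) {
  print(object, ...)
  sig <- object$terms$p < object$family_alpha
  cat(sprintf("%d of %d terms significant at the family-adjusted alpha\n",
              sum(sig, na.rm = TRUE), nrow(object$terms)))
  invisible(object)
}

#' @exportS3Method stats::coef
coef.swap_fit <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

# offers table joined with participant covariates, factors releveled to the
# trial's reference categories (health frame, female, Bachelor's degree,
# income under 15,500)
merged_offers <- function(dataset) {
  if (inherits(dataset, "trial_data")) {
    p <- dataset$participants
    keep <- if (all(is.na(p$included))) rep(TRUE, nrow(p)) else p$included
    p <- p[keep, , drop = FALSE]
    o <- dataset$offers[dataset$offers$participant_id %in% p$participant_id, ,
                        drop = FALSE]
    cov_cols <- intersect(c("participant_id", "age", "gender", "bmi",
                            "education", "income", "shopping_responsibility"),
                          names(p))
    df <- merge(o, p[, cov_cols, drop = FALSE], by = "participant_id",
                sort = FALSE)
  } else {
    df <- as.data.frame(dataset)
  }
  if (!nrow(df)) fail("no offers")
  df$frame <- factor(df$frame, levels = frame_levels)
  if ("gender" %in% names(df)) df$gender <- factor(df$gender, levels = c("female", "male"))
  if ("education" %in% names(df)) {
    df$education <- stats::relevel(factor(df$education, levels = education_levels),
                                   ref = "bachelors")
  }
  if ("income" %in% names(df)) df$income <- factor(df$income, levels = income_levels)
  if ("shopping_responsibility" %in% names(df)) {
    df$shopping_responsibility <- factor(df$shopping_responsibility,
                                         levels = c("half", "full"))
  }
  df
}

coef_table <- function(coefs) {
  data.frame(term = rownames(coefs),
             estimate = coefs[, 1L], se = coefs[, 2L],
             statistic = coefs[, 3L],
             p = coefs[, ncol(coefs)],
             stringsAsFactors = FALSE)
}

check_degenerate_glm <- function(fit) {
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    fail("rank-deficient model; aliased term(s): %s",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  huge <- names(cf)[abs(cf) > 10 & names(cf) != "(Intercept)"]
  mu <- stats::fitted(fit)
  if (length(huge) && (any(mu > 1 - 1e-8) || any(mu < 1e-8))) {
    fail("complete or quasi-complete separation; suspect term(s): %s",
         paste(huge, collapse = ", "))
  }
  invisible(fit)
}

# try an lme4 fit; return NULL when it errors, fails to converge or is
# singular, so the caller can fall back to the fixed-effect model
try_mixed <- function(expr) {
  fit <- tryCatch(withCallingHandlers(
    expr,
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  ), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  conv <- fit@optinfo$conv
  ok <- length(conv$lme4) == 0L && isTRUE(conv$opt == 0) &&
    !lme4::isSingular(fit, tol = 1e-4)
  if (ok) fit else NULL
}

#' Fit the primary swap-acceptance logistic model
#'
#' Binary logistic regression of offer acceptance. The unadjusted model has
#' the message frame plus two controls (number of alternatives shown in the
#' offer, number of offers the shopper received); the adjusted model adds
#' age, gender, BMI, education, income, shopping responsibility and the
#' frame-by-income interaction. Reference levels: health frame, female,
#' Bachelor's degree, income under 15,500. When `allow_random_intercept` is
#' on, a participant-level random intercept is attempted first
#' (`lme4::glmer`) and the model falls back to the fixed-effect fit when the
#' mixed fit does not converge, with the fallback flagged on the result.
#' Both primary models form one Bonferroni family, so `family_alpha`
#' defaults to 0.025.
#'
#' @param dataset A `trial_data` object or a pre-merged offers data.frame
#'   (needs `accepted`, `frame`, `n_alternatives`,
#'   `n_offers_for_participant`, and the covariates for the adjusted
#'   model).
#' @param adjusted Fit the adjusted specification (default `FALSE`).
#' @param allow_random_intercept Attempt the participant random intercept
#'   (default: only for the adjusted model, the specification for which the
#'   multilevel fit was planned).
#' @param intercept_only Fit the intercept-only null model (overrides the
#'   other specification switches).
#' @param family_alpha Family-adjusted significance threshold.
#' @return A `swap_fit`.
#' @export
fit_acceptance_model <- function(dataset, adjusted = FALSE,
                                 allow_random_intercept = adjusted,
                                 intercept_only = FALSE,
                                 family_alpha = bonferroni_alpha(0.05, 2)) {
  df <- merged_offers(dataset)
  y <- df$accepted
  if (all(y == y[1L])) {
    fail("degenerate outcome: every offer was %s",
         if (y[1L]) "accepted" else "kept")
  }
  main_terms <- if (intercept_only) {
    character(0)
  } else if (adjusted) {
    c("n_alternatives", "n_offers_for_participant", "frame", "age", "gender",
      "bmi", "education", "income", "shopping_responsibility")
  } else {
    c("n_alternatives", "n_offers_for_participant", "frame")
  }
  # drop terms that cannot be estimated on this dataset (single observed
  # level or constant column), e.g. in single-frame toy tables
  estimable <- vapply(main_terms, function(v) {
    x <- df[[v]]
    if (is.factor(x) || is.character(x)) {
      length(unique(as.character(x[!is.na(x)]))) > 1L
    } else {
      stats::var(x, na.rm = TRUE) > 0
    }
  }, logical(1L))
  dropped <- main_terms[!estimable]
  main_terms <- main_terms[estimable]
  if (adjusted && all(c("frame", "income") %in% main_terms)) {
    main_terms <- c(main_terms, "frame:income")
  }
  rhs <- if (length(main_terms)) paste(main_terms, collapse = " + ") else "1"
  label <- if (intercept_only) "acceptance (intercept only)"
  else if (adjusted) "acceptance (adjusted)" else "acceptance (unadjusted)"
  fallback <- FALSE
  fit <- NULL
  if (allow_random_intercept && !intercept_only) {
    fit <- try_mixed(lme4::glmer(
      stats::as.formula(paste("accepted ~", rhs, "+ (1 | participant_id)")),
      data = df, family = stats::binomial()))
    if (is.null(fit)) fallback <- TRUE
  }
  if (is.null(fit)) {
    fit <- stats::glm(stats::as.formula(paste("accepted ~", rhs)),
                      data = df, family = stats::binomial())
    check_degenerate_glm(fit)
    terms <- coef_table(stats::coef(summary(fit)))
  } else {
    terms <- coef_table(stats::coef(summary(fit)))
  }
  out <- new_swap_fit(terms, label, family_alpha, converged = TRUE,
                      fallback = fallback, fit = fit)
  out$dropped_terms <- dropped
  out
}

#' Long offer-by-time table for the energy-change models
#'
#' Two rows per offer: the original pack energy at time 0 and, at time 1,
#' the final purchase (`original_vs_final`), the top-ranked alternative
#' (`original_vs_alternative`), or rows contrasting final purchases with the
#' alternative (`final_vs_alternative`).
#'
#' @param dataset A `trial_data` object.
#' @param comparison Which pair of time points to contrast.
#' @return A long data.frame with `offer_id`, `participant_id`, `frame`,
#'   `time` (0/1), `kcal`, and the two controls.
#' @export
energy_long <- function(dataset,
                        comparison = c("original_vs_final",
                                       "original_vs_alternative",
                                       "final_vs_alternative")) {
  comparison <- match.arg(comparison)
  df <- merged_offers(dataset)
  final_kcal <- df$original_kcal + df$observed_delta_kcal
  alt_kcal <- df$original_kcal + df$potential_delta_kcal
  kcal0 <- switch(comparison,
                  original_vs_final = df$original_kcal,
                  original_vs_alternative = df$original_kcal,
                  final_vs_alternative = final_kcal)
  kcal1 <- switch(comparison,
                  original_vs_final = final_kcal,
                  original_vs_alternative = alt_kcal,
                  final_vs_alternative = alt_kcal)
  long <- data.frame(
    offer_id = rep(df$offer_id, 2L),
    participant_id = rep(df$participant_id, 2L),
    frame = rep(as.character(df$frame), 2L),
    time = rep(c(0L, 1L), each = nrow(df)),
    kcal = c(kcal0, kcal1),
    n_alternatives = rep(df$n_alternatives, 2L),
    n_offers_for_participant = rep(df$n_offers_for_participant, 2L),
    stringsAsFactors = FALSE
  )
  rownames(long) <- NULL
  long
}

validate_energy_long <- function(long) {
  need <- c("offer_id", "participant_id", "frame", "time", "kcal",
            "n_alternatives", "n_offers_for_participant")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols)) {
    fail("long table missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  counts <- table(long$offer_id, long$time)
  if (!all(dim(counts) == c(length(unique(long$offer_id)), 2L)) ||
      !all(counts == 1L)) {
    fail("malformed long table: every offer needs exactly one row per time level")
  }
  long
}

#' Fit a per-swap energy-change model
#'
#' Multilevel linear regression of pack energy on a time dummy (0 = the
#' earlier choice, 1 = the later/counterfactual one), with swaps nested in
#' participants via a random intercept (`lmerTest::lmer`, Satterthwaite
#' degrees of freedom) and a fixed-effect `lm` fallback when the mixed model
#' does not converge. Controls: alternatives shown per offer, offers per
#' shopper. With `by_frame` the model adds frame main effects and
#' frame-by-time interactions, testing whether the energy change is
#' moderated by the message frame. Two analyses per outcome form one
#' Bonferroni family (`family_alpha` 0.025).
#'
#' @param dataset A `trial_data` object, or a prebuilt long table as from
#'   [energy_long()].
#' @param comparison Passed to [energy_long()] when `dataset` is a
#'   `trial_data`.
#' @param by_frame Add frame-by-time moderation terms.
#' @param allow_random_intercept Attempt the participant random intercept
#'   (default `TRUE`).
#' @param family_alpha Family-adjusted significance threshold.
#' @return A `swap_fit`; the `time` coefficient is the mean kcal change.
#' @export
fit_energy_change_model <- function(dataset,
                                    comparison = c("original_vs_final",
                                                   "original_vs_alternative",
                                                   "final_vs_alternative"),
                                    by_frame = FALSE,
                                    allow_random_intercept = TRUE,
                                    family_alpha = bonferroni_alpha(0.05, 2)) {
  long <- if (inherits(dataset, "trial_data")) {
    energy_long(dataset, comparison)
  } else {
    validate_energy_long(as.data.frame(dataset))
  }
  long$frame <- factor(long$frame, levels = frame_levels)
  rhs <- if (by_frame) {
    "time * frame + n_alternatives + n_offers_for_participant"
  } else {
    "time + n_alternatives + n_offers_for_participant"
  }
  label <- sprintf("energy change (%s%s)",
                   if (inherits(dataset, "trial_data")) match.arg(comparison)
                   else "long table",
                   if (by_frame) ", by frame" else "")
  fallback <- FALSE
  fit <- NULL
  if (allow_random_intercept) {
    fit <- try_mixed(lmerTest::lmer(
      stats::as.formula(paste("kcal ~", rhs, "+ (1 | participant_id)")),
      data = long))
    if (is.null(fit)) fallback <- TRUE
  }
  if (is.null(fit)) {
    fit <- stats::lm(stats::as.formula(paste("kcal ~", rhs)), data = long)
    terms <- coef_table(stats::coef(summary(fit)))
  } else {
    cf <- stats::coef(summary(fit)) # estimate, se, df, t, p
    terms <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"], statistic = cf[, "t value"],
                        p = cf[, "Pr(>|t|)"], stringsAsFactors = FALSE)
  }
  new_swap_fit(terms, label, family_alpha, fallback = fallback, fit = fit)
}

paired_fit <- function(diffs, label, family_alpha) {
  if (length(diffs) < 2L || stats::sd(diffs) == 0) {
    fail("degenerate input for %s: paired differences have zero variance", label)
  }
  tt <- stats::t.test(diffs)
  new_swap_fit(
    data.frame(term = label, estimate = unname(tt$estimate),
               se = unname(tt$stderr), statistic = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE),
    model_label = sprintf("paired t: %s", label),
    family_alpha = family_alpha)
}

#' Paired basket-level tests
#'
#' Paired t-tests (df = n - 1, two-sided) of per-basket change scores:
#' observed kcal change (final - baseline), potential kcal change
#' (all-swaps-accepted - baseline), and - when nutrient totals are present -
#' grams of saturated fat, sugar and salt. Three analyses were performed on
#' observed basket energy and three on the nutrients, so both families use a
#' 0.05/3 = .017 threshold.
#'
#' @param baskets The `baskets` table of a `trial_data` (or the object
#'   itself).
#' @param family_alpha Family-adjusted threshold (default
#'   `bonferroni_alpha(0.05, 3)`).
#' @return Named list of `swap_fit` objects.
#' @export
basket_change_tests <- function(baskets,
                                family_alpha = bonferroni_alpha(0.05, 3)) {
  if (inherits(baskets, "trial_data")) baskets <- baskets$baskets
  out <- list(
    kcal_observed = paired_fit(baskets$final_kcal - baskets$baseline_kcal,
                               "kcal_observed", family_alpha),
    kcal_potential = paired_fit(baskets$potential_kcal - baskets$baseline_kcal,
                                "kcal_potential", family_alpha)
  )
  for (nm in c("sat_fat_g", "sugar_g", "salt_g")) {
    fcol <- paste0("final_", nm)
    bcol <- paste0("baseline_", nm)
    if (all(c(fcol, bcol) %in% names(baskets))) {
      out[[nm]] <- paired_fit(baskets[[fcol]] - baskets[[bcol]], nm,
                              family_alpha)
    }
  }
  out
}

#' Regression of basket energy change on message frame
#'
#' Ordinary least squares of the per-basket kcal change (final - baseline)
#' on frame dummies (health as baseline); the adjusted model adds age,
#' gender, BMI, education and income.
#'
#' @param dataset A `trial_data` object (demographics are merged from the
#'   participants table), or a baskets data.frame already carrying the
#'   needed columns.
#' @param adjusted Add the demographic covariates.
#' @param family_alpha Family-adjusted threshold (default
#'   `bonferroni_alpha(0.05, 3)`, the observed basket-change family).
#' @return A `swap_fit`.
#' @export
basket_change_regression <- function(dataset, adjusted = FALSE,
                                     family_alpha = bonferroni_alpha(0.05, 3)) {
  if (inherits(dataset, "trial_data")) {
    b <- dataset$baskets
    p <- dataset$participants
    df <- merge(b, p[, intersect(c("participant_id", "age", "gender", "bmi",
                                   "education", "income"), names(p))],
                by = "participant_id", sort = FALSE)
  } else {
    df <- as.data.frame(dataset)
  }
  df$change <- df$final_kcal - df$baseline_kcal
  if (stats::sd(df$change) == 0) fail("constant outcome: basket change has zero variance")
  df$arm <- factor(df$arm, levels = frame_levels)
  if (adjusted) {
    df$gender <- factor(df$gender, levels = c("female", "male"))
    df$education <- stats::relevel(factor(df$education, levels = education_levels),
                                   ref = "bachelors")
    df$income <- factor(df$income, levels = income_levels)
  }
  rhs <- if (adjusted) "arm + age + gender + bmi + education + income" else "arm"
  fit <- stats::lm(stats::as.formula(paste("change ~", rhs)), data = df)
  new_swap_fit(coef_table(stats::coef(summary(fit))),
               sprintf("basket change (%s)", if (adjusted) "adjusted" else "frame only"),
               family_alpha, fit = fit)
}

#' Randomisation balance checks
#'
#' Chi-square tests of arm against the categorical baseline factors (gender,
#' education, income) and one-way ANOVAs of the continuous ones (age, BMI,
#' and baseline basket kcal when available).
#'
#' @param dataset A `trial_data` object or a participants data.frame with an
#'   `arm` column.
#' @param included_only Restrict to included participants when the flag is
#'   present (default `TRUE`).
#' @return A data.frame with one row per check: `variable`, `test`,
#'   `statistic`, `df`, `p`.
#' @export
balance_checks <- function(dataset, included_only = TRUE) {
  if (inherits(dataset, "trial_data")) {
    p <- dataset$participants
    if (!is.null(dataset$baskets)) {
      p <- merge(p, dataset$baskets[, c("participant_id", "baseline_kcal")],
                 by = "participant_id", all.x = TRUE, sort = FALSE)
    }
  } else {
    p <- as.data.frame(dataset)
  }
  if (included_only && "included" %in% names(p) && !all(is.na(p$included))) {
    p <- p[p$included, , drop = FALSE]
  }
  if (length(unique(p$arm[!is.na(p$arm)])) < 2L) {
    fail("balance checks need at least two arms")
  }
  rows <- list()
  for (v in intersect(c("gender", "education", "income"), names(p))) {
    tab <- table(p$arm, p[[v]])
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[v]] <- data.frame(variable = v, test = "chi_square",
                            statistic = unname(ct$statistic),
                            df = unname(ct$parameter), p = ct$p.value,
                            stringsAsFactors = FALSE)
  }
  for (v in intersect(c("age", "bmi", "baseline_kcal"), names(p))) {
    fit <- stats::aov(p[[v]] ~ factor(p$arm))
    s <- summary(fit)[[1L]]
    rows[[v]] <- data.frame(variable = v, test = "anova_F",
                            statistic = s[["F value"]][1L],
                            df = s[["Df"]][1L], p = s[["Pr(>F)"]][1L],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive summary of a trial dataset
#'
#' Offer and acceptance counts and percentages, overall and per arm;
#' participants accepting at least one offer; offers per participant; mean
#' observed and potential per-offer energy changes; and, when a baskets
#' table is present, mean per-basket observed and potential reductions.
#' Percentages follow the trial's reporting convention (print method rounds
#' to 2 decimals; per-participant shares to 1).
#'
#' @param dataset A `trial_data` object.
#' @return An object of class `swap_summary`.
#' @export
descriptives <- function(dataset) {
  p <- dataset$participants
  keep <- if (all(is.na(p$included))) rep(TRUE, nrow(p)) else p$included
  p <- p[keep, , drop = FALSE]
  o <- dataset$offers[dataset$offers$participant_id %in% p$participant_id, ,
                      drop = FALSE]
  if (nrow(o) == 0L) fail("no offers")
  acc_by <- stats::setNames(rep(0L, nrow(p)), p$participant_id)
  tab <- table(o$participant_id[o$accepted])
  acc_by[names(tab)] <- as.integer(tab)
  noff_by <- stats::setNames(rep(0L, nrow(p)), p$participant_id)
  tab <- table(o$participant_id)
  noff_by[names(tab)] <- as.integer(tab)

  arm_stats <- function(frame) {
    oo <- if (is.null(frame)) o else o[o$frame == frame, , drop = FALSE]
    pp <- if (is.null(frame)) p else p[p$arm == frame, , drop = FALSE]
    acc <- acc_by[pp$participant_id]
    data.frame(
      arm = if (is.null(frame)) "overall" else frame,
      offers = nrow(oo),
      accepted = sum(oo$accepted),
      acceptance_pct = 100 * sum(oo$accepted) / nrow(oo),
      participants = nrow(pp),
      accepting_participants = sum(acc > 0L),
      accepting_pct = 100 * sum(acc > 0L) / nrow(pp),
      stringsAsFactors = FALSE
    )
  }
  by_arm <- do.call(rbind, lapply(frame_levels, arm_stats))
  overall <- arm_stats(NULL)
  baskets <- NULL
  if (!is.null(dataset$baskets) && nrow(dataset$baskets)) {
    b <- dataset$baskets
    baskets <- list(
      mean_observed_reduction_kcal = mean(b$baseline_kcal - b$final_kcal),
      mean_potential_reduction_kcal = mean(b$baseline_kcal - b$potential_kcal),
      mean_baseline_kcal = mean(b$baseline_kcal)
    )
  }
  structure(list(
    overall = overall,
    by_arm = by_arm,
    offers_per_participant = c(mean = mean(noff_by), sd = stats::sd(noff_by)),
    per_offer = c(mean_observed_delta_kcal = mean(o$observed_delta_kcal),
                  mean_potential_delta_kcal = mean(o$potential_delta_kcal)),
    baskets = baskets
  ), class = "swap_summary")
}

#' @exportS3Method print swap_summary
print.swap_summary <- function(x, ...) {
  ov <- x$overall
  cat(sprintf("Swap offers: %d, accepted %d (%.2f%%)\n",
              ov$offers, ov$accepted, ov$acceptance_pct))
  cat(sprintf("Participants: %d, accepting >=1 swap: %d (%.1f%%)\n",
              ov$participants, ov$accepting_participants, ov$accepting_pct))
  cat(sprintf("Offers per participant: M = %.2f, SD = %.2f\n",
              x$offers_per_participant["mean"], x$offers_per_participant["sd"]))
  tab <- x$by_arm
  tab$acceptance_pct <- round(tab$acceptance_pct, 2)
  tab$accepting_pct <- round(tab$accepting_pct, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("Per offer: observed %.2f kcal, potential %.2f kcal\n",
              x$per_offer["mean_observed_delta_kcal"],
              x$per_offer["mean_potential_delta_kcal"]))
  if (!is.null(x$baskets)) {
    cat(sprintf("Per basket: observed reduction %.2f kcal, potential reduction %.2f kcal\n",
                x$baskets$mean_observed_reduction_kcal,
                x$baskets$mean_potential_reduction_kcal))
  }
  invisible(x)
}
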