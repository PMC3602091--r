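# The four outcome models. Employment and SSI receipt are logistic
# regressions on all adults; household income is ordinary least squares and
# missed work days a negative-binomial (log link, quadratic variance)
# regression, both on the employed population.

new_msk_fit <- function(model, outcome, specification, n, fit_stat) {
  sm <- summary(model)
  ct <- sm$coefficients
  est <- ct[, 1]
  se <- ct[, 2]
  pval <- ct[, 4]
  exp_est <- if (outcome == "income") est else exp(est)
  table <- data.frame(
    term = rownames(ct),
    estimate = unname(est),
    se = unname(se),
    p_value = unname(pval),
    exp_estimate = unname(exp_est),
    significant = unname(pval < 0.05),
    row.names = NULL)
  structure(list(
    outcome = outcome,
    specification = specification,
    table = table,
    n = n,
    fit_stat = fit_stat,
    dispersion = if (inherits(model, "negbin")) 1 / model$theta else NULL,
    theta = if (inherits(model, "negbin")) model$theta else NULL,
    model = model), class = "msk_fit")
}

#' @export
print.msk_fit <- function(x, ...) {
  scale_lab <- switch(x$outcome,
                      employment = , ssi = "odds ratio",
                      income = "dollars",
                      missed_days = "rate ratio")
  cat(sprintf("Outcome: %s  (specification: %s, n = %d)\n",
              x$outcome, x$specification, x$n))
  cat(sprintf("Effects reported as %s; '*' marks p < 0.05\n\n", scale_lab))
  tab <- x$table
  tab$effect <- sprintf("%s%s",
                        ifelse(x$outcome == "income",
                               sprintf("%.0f", tab$exp_estimate),
                               sprintf("%.2f", tab$exp_estimate)),
                        ifelse(tab$significant, "*", ""))
  print(tab[, c("term", "effect", "se", "p_value")], digits = 3)
  if (!is.null(x$dispersion)) {
    cat(sprintf("\nDispersion (1/theta): %.3f\n", x$dispersion))
  }
  invisible(x)
}

outcome_response <- function(outcome) {
  switch(outcome, employment = "employed", ssi = "ssi",
         income = "income_mid", missed_days = "missed_days")
}

fit_formula <- function(outcome, terms) {
  if (!length(terms)) terms <- "1"
  stats::reformulate(terms, response = outcome_response(outcome))
}

#' Fit the logistic outcome models
#'
#' Maximum-likelihood logistic regression of employment or SSI receipt on
#' the design's covariates, over all adults. Effects are reported as odds
#' ratios.
#'
#' @param design an `msk_design` from [expand_design()].
#' @param outcome `"employment"` or `"ssi"`.
#' @return An object of class `msk_fit` with a per-covariate coefficient
#'   table (`table`: estimate, standard error, p-value, odds ratio), the
#'   population size `n`, the fitted model and a likelihood-based fit
#'   statistic.
#' @export
fit_logistic <- function(design, outcome = c("employment", "ssi")) {
  outcome <- match.arg(outcome)
  df <- design_population(design, outcome)
  terms <- design_terms(design$specification, FALSE)
  df <- merge_empty_levels(df, terms)
  fml <- fit_formula(outcome, active_terms(df, terms))
  fit <- stats::glm(fml, data = df, family = stats::binomial())
  if (!fit$converged) {
    stop(sprintf("logistic %s model did not converge (deviance %.2f after %d iterations); check for separation or empty cells",
                 outcome, fit$deviance, fit$iter), call. = FALSE)
  }
  mu <- stats::fitted(fit)
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    stop(sprintf("logistic %s model shows signs of complete separation: fitted probabilities of 0 or 1 (range %.2g to %.2g)",
                 outcome, min(mu), max(mu)), call. = FALSE)
  }
  new_msk_fit(fit, outcome, design$specification, nrow(df),
              c(logLik = as.numeric(stats::logLik(fit))))
}

#' Fit the household income model
#'
#' Ordinary least squares regression of CPI-adjusted midpoint household
#' income (2010 dollars) on the design's covariates, over the employed
#' population. Coefficients are on the dollar scale.
#'
#' @param design an `msk_design` from [expand_design()].
#' @return An `msk_fit`; `fit_stat` carries the R-squared.
#' @export
fit_income <- function(design) {
  df <- design_population(design, "income")
  terms <- design_terms(design$specification, TRUE)
  df <- merge_empty_levels(df, terms)
  fml <- fit_formula("income", active_terms(df, terms))
  fit <- stats::lm(fml, data = df)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    stop(sprintf("income design is rank deficient; aliased column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  new_msk_fit(fit, "income", design$specification, nrow(df),
              c(r_squared = summary(fit)$r.squared))
}

#' Fit the missed-work-days model
#'
#' Negative-binomial regression (log link, quadratic variance function,
#' dispersion estimated by maximum likelihood) of capped annual missed work
#' days on the design's covariates, over the employed population. Effects
#' are reported as rate ratios; the fit records the estimated dispersion
#' (1/theta, approaching 0 as the counts approach Poisson).
#'
#' @param design an `msk_design` from [expand_design()].
#' @return An `msk_fit` with `dispersion` and `theta` components.
#' @export
fit_missed_days <- function(design) {
  df <- design_population(design, "missed_days")
  terms <- design_terms(design$specification, TRUE)
  df <- merge_empty_levels(df, terms)
  fml <- fit_formula("missed_days", active_terms(df, terms))
  # theta iteration warnings are expected near the Poisson limit
  fit <- withCallingHandlers(
    MASS::glm.nb(fml, data = df),
    warning = function(w) {
      if (grepl("iteration limit reached", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop(sprintf("negative-binomial missed-days model did not converge; final deviance %.2f, theta %.3g (trace: %d IRLS iterations)",
                 fit$deviance, fit$theta, fit$iter), call. = FALSE)
  }
  new_msk_fit(fit, "missed_days", design$specification, nrow(df),
              c(logLik = as.numeric(stats::logLik(fit))))
}

#' Fit any of the four outcome models
#'
#' Dispatcher over [fit_logistic()], [fit_income()] and
#' [fit_missed_days()].
#'
#' @param design an `msk_design`.
#' @param outcome one of `"employment"`, `"ssi"`, `"income"`,
#'   `"missed_days"`.
#' @return An `msk_fit`.
#' @export
fit_outcome <- function(design, outcome) {
  outcome <- match.arg(outcome, msk_outcomes)
  switch(outcome,
         employment = fit_logistic(design, "employment"),
         ssi = fit_logistic(design, "ssi"),
         income = fit_income(design),
         missed_days = fit_missed_days(design))
}

#' Tabulate fitted effects across outcomes
#'
#' Combines several fits into one wide table in the layout of the published
#' regression tables: one row per covariate, one column per outcome, effects
#' on the reporting scale (odds ratios, dollars, rate ratios) with `*`
#' marking p < 0.05.
#'
#' @param fits a list of `msk_fit` objects.
#' @return A data frame with a `term` column and one character column per
#'   fit.
#' @export
format_results_table <- function(fits) {
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  terms <- unique(unlist(lapply(fits, function(f) f$table$term)))
  out <- data.frame(term = terms)
  for (f in fits) {
    fmt <- ifelse(f$outcome == "income", "%.0f", "%.2f")
    eff <- sprintf(paste0(fmt, "%s"), f$table$exp_estimate,
                   ifelse(f$table$significant, "*", ""))
    out[[paste(f$outcome, f$specification, sep = ".")]] <-
      eff[match(terms, f$table$term)]
  }
  out
}

#' Simulate a functional-improvement scenario under both specifications
#'
#' Fits all four outcome models under the full and the index specification
#' on the same cohort, applies a functional-improvement recode — every
#' respondent who finds walking, climbing or stooping very difficult or
#' impossible (codes 4-5) improves to "somewhat difficult" (code 3) — and
#' re-predicts the outcomes under both fitted specifications. Reports the
#' change in the labor-force participation rate overall and by age band, and
#' the direction of change for each outcome, as a check that the compact
#' index specification and the 32-indicator full specification tell the same
#' story.
#'
#' @param cohort a cohort data frame.
#' @param config a preprocessing configuration.
#' @param recode_items items whose severe codes are improved.
#' @param improve_from codes treated as severe.
#' @param improve_to the improved code.
#' @param outcomes which outcomes to fit and re-predict; participation
#'   requires `"employment"`.
#' @return A list of class `msk_spec_comparison` with elements
#'   `participation` (per-spec baseline, scenario and change, percentage
#'   points), `participation_by_age`, `outcome_changes` (per outcome and
#'   spec) and the fitted models.
#' @export
compare_specifications <- function(cohort,
                                   config = default_preprocess_config(),
                                   recode_items = c("walk", "climb", "stoop"),
                                   improve_from = c(4L, 5L),
                                   improve_to = 3L,
                                   outcomes = msk_outcomes) {
  outcomes <- match.arg(outcomes, msk_outcomes, several.ok = TRUE)
  improved <- cohort
  for (it in recode_items) {
    col <- paste0("lim_", it)
    sel <- improved[[col]] %in% improve_from
    improved[[col]][sel] <- improve_to
  }

  specs <- c("full", "index")
  fits <- list()
  pred <- list()
  for (sp in specs) {
    design <- expand_design(cohort, sp, config = config)
    design_new <- expand_design(improved, sp, config = config)
    fits[[sp]] <- lapply(stats::setNames(outcomes, outcomes),
                         function(oc) fit_outcome(design, oc))
    pred[[sp]] <- lapply(stats::setNames(outcomes, outcomes),
                         function(oc) {
      base_df <- design_population(design, oc)
      new_df <- design_population(design_new, oc)
      model <- fits[[sp]][[oc]]$model
      list(base = stats::predict(model, newdata = base_df,
                                 type = "response"),
           new = stats::predict(model, newdata = new_df,
                                type = "response"),
           age = base_df$age_group)
    })
  }

  participation <- NULL
  by_age <- NULL
  if ("employment" %in% outcomes) {
    participation <- do.call(rbind, lapply(specs, function(sp) {
      p <- pred[[sp]]$employment
      data.frame(specification = sp,
                 baseline_pct = 100 * mean(p$base),
                 scenario_pct = 100 * mean(p$new),
                 change_pp = 100 * (mean(p$new) - mean(p$base)))
    }))
    by_age <- do.call(rbind, lapply(specs, function(sp) {
      p <- pred[[sp]]$employment
      agg <- tapply(p$new - p$base, p$age, mean)
      data.frame(specification = sp, age_group = names(agg),
                 change_pp = 100 * as.numeric(agg), row.names = NULL)
    }))
  }

  outcome_changes <- do.call(rbind, lapply(specs, function(sp) {
    do.call(rbind, lapply(outcomes, function(oc) {
      p <- pred[[sp]][[oc]]
      data.frame(specification = sp, outcome = oc,
                 change = mean(p$new) - mean(p$base))
    }))
  }))

  structure(list(participation = participation,
                 participation_by_age = by_age,
                 outcome_changes = outcome_changes,
                 fits = fits), class = "msk_spec_comparison")
}

#' @export
print.msk_spec_comparison <- function(x, ...) {
  cat("Functional-improvement scenario: full vs index specification\n\n")
  print(x$participation, digits = 5)
  cat("\nOutcome changes (response scale):\n")
  print(x$outcome_changes, digits = 4)
  invisible(x)
}
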