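# Scenario engine: apply published (or fitted) effects to a covariate
# profile to predict the four economic outcomes. Published effects act on
# the reporting scales: odds ratios multiply the baseline odds, rate ratios
# multiply the expected count, dollar effects add to baseline income.

#' Move a probability by an odds ratio
#'
#' Converts a baseline probability to odds, multiplies by an odds ratio and
#' converts back. Several simultaneous effects are composed by multiplying
#' their odds ratios first; `apply_odds_ratio` is consistent with that
#' composition: `apply_odds_ratio(apply_odds_ratio(p, a), b)` equals
#' `apply_odds_ratio(p, a * b)`.
#'
#' @param p0 baseline probability, strictly inside (0, 1).
#' @param or a positive odds ratio (or a vector of them, applied
#'   elementwise).
#' @return The shifted probability.
#' @export
#' @examples
#' apply_odds_ratio(0.61, 0.84)  # about 0.568
apply_odds_ratio <- function(p0, or) {
  if (any(!is.finite(p0)) || any(p0 <= 0) || any(p0 >= 1)) {
    stop("baseline probability must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (any(!is.finite(or)) || any(or <= 0)) {
    stop("odds ratio must be positive", call. = FALSE)
  }
  odds <- or * p0 / (1 - p0)
  odds / (1 + odds)
}

#' Published regression effects
#'
#' Loads the transcription of the published effect tables bundled with the
#' package: odds ratios (employment, SSI receipt), dollar coefficients
#' (household income) and rate ratios (missed work days) per covariate, for
#' either the full per-item specification or the index specification.
#'
#' @param specification `"full"` or `"index"`.
#' @return A data frame with columns `term_type`, `key`, `level` and one
#'   numeric column per outcome. Cells the source table leaves blank are
#'   `NA`.
#' @export
published_effects <- function(specification = c("full", "index")) {
  specification <- match.arg(specification)
  path <- system.file("extdata",
                      paste0("published_effects_", specification, ".csv"),
                      package = "mskecon", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(level = "character"))
}

#' Reference covariate profile and baseline outcomes
#'
#' `reference_profile()` is the worked-example reference person: a man aged
#' 60-64 interviewed in 2010, at the reference education and occupation,
#' with no activity limitations. `baseline_outcomes()` returns that
#' profile's baseline outcomes: employment probability 0.61 and SSI
#' probability 0.045 (published alongside the worked examples), 2.5 expected
#' missed work days (the published "2-3 days"), and household income
#' computed from the published intercept and coefficients of the chosen
#' specification.
#'
#' @param specification which published income equation to evaluate.
#' @return `reference_profile()`: an `msk_profile`; `baseline_outcomes()`: a
#'   list with `employment`, `ssi`, `income`, `missed_days` and the
#'   `profile` the baselines refer to.
#' @export
reference_profile <- function() {
  covariate_profile()
}

#' @rdname reference_profile
#' @export
baseline_outcomes <- function(specification = c("full", "index")) {
  specification <- match.arg(specification)
  eff <- published_effects(specification)
  val <- function(tt, k) {
    eff$income[eff$term_type == tt & eff$key == k]
  }
  income <- val("intercept", "intercept") + val("sex", "male") +
    val("age", "60-64")
  if (specification == "index") {
    income <- income + 100 * eff$income[eff$term_type == "index"]
  }
  list(employment = 0.61, ssi = 0.045, income = unname(income),
       missed_days = 2.5, profile = reference_profile())
}

#' Build a covariate profile
#'
#' A scenario description fed to [predict_profile()]: demographics plus
#' either per-item limitation levels (full specification) or an index value
#' with sitting/reaching/standing levels (index specification). Items left
#' at 1 mean "not at all difficult".
#'
#' @param age_group,sex,education,occupation,year demographics; defaults are
#'   the reference person of the worked examples.
#' @param items named integer vector of limitation codes (subset of
#'   `walk`, `climb`, `sit`, `reach`, `stand`, `stoop`, `lift`, `push`,
#'   values 1-5); unnamed items default to 1.
#' @param index optional Physical Function Index value in [100/3, 100]. If
#'   omitted it is computed from the items.
#' @param causes character vector of attributed causes among `back`,
#'   `injury`, `msk`, `arthritis`.
#' @return An object of class `msk_profile`.
#' @export
#' @examples
#' covariate_profile(items = c(walk = 3))
covariate_profile <- function(age_group = "60-64", sex = "male",
                              education = "no_hs", occupation = "unknown",
                              year = 2010, items = integer(), index = NULL,
                              causes = character()) {
  age_group <- match.arg(age_group, msk_age_levels)
  sex <- match.arg(sex, msk_sex_levels)
  education <- match.arg(education, msk_education_levels)
  occupation <- match.arg(occupation, msk_occupation_levels)
  if (!year %in% msk_years) stop("year must be 2004-2010", call. = FALSE)
  full_items <- stats::setNames(rep(1L, length(msk_items)), msk_items)
  if (length(items)) {
    bad <- setdiff(names(items), msk_items)
    if (length(bad)) {
      stop(sprintf("unknown limitation item(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (any(!items %in% 1:5)) {
      stop("limitation codes must be 1-5", call. = FALSE)
    }
    full_items[names(items)] <- as.integer(items)
  }
  if (!is.null(index) && (index < 100 / 3 - 1e-9 || index > 100 + 1e-9)) {
    stop("index value must lie in [33.33, 100]", call. = FALSE)
  }
  bad_cause <- setdiff(causes, msk_causes)
  if (length(bad_cause)) {
    stop(sprintf("unknown cause(s): %s", paste(bad_cause, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(age_group = age_group, sex = sex, education = education,
                 occupation = occupation, year = as.integer(year),
                 items = full_items, index = index, causes = causes),
            class = "msk_profile")
}

profile_index <- function(profile, mapping = default_index_mapping()) {
  if (!is.null(profile$index)) return(profile$index)
  r <- as.list(stats::setNames(profile$items, paste0("lim_", msk_items)))
  score_index(r, mapping = mapping, msk_only = FALSE)$value
}

#' Pre-surgery limitation profiles of joint-replacement candidates
#'
#' Surgeon-consensus presets describing candidates for elective knee
#' replacement: such patients find it somewhat-to-very difficult to walk a
#' quarter-mile, climb 10 steps, sit for two hours, stand for two hours,
#' stoop, lift 10 pounds, and push or pull large objects (overhead reaching
#' is not part of the consensus list). The two presets place all seven items
#' at "somewhat difficult" (code 3) or "very difficult" (code 4); together
#' they bracket the published 21-25\% employment range for such candidates.
#'
#' @param preset `"tkr_candidate_somewhat"` or `"tkr_candidate_very"`.
#' @return An `msk_profile` with the reference demographics.
#' @export
#' @examples
#' combined_limitation_profile("tkr_candidate_somewhat")
combined_limitation_profile <- function(preset = c("tkr_candidate_somewhat",
                                                   "tkr_candidate_very")) {
  preset <- match.arg(preset)
  level <- if (preset == "tkr_candidate_somewhat") 3L else 4L
  affected <- setdiff(msk_items, "reach")
  covariate_profile(items = stats::setNames(rep(level, length(affected)),
                                            affected))
}

#' Predict the four outcomes for a covariate profile
#'
#' In `published` mode, composes printed effects onto the baseline
#' outcomes: odds ratios for every covariate where the profile departs from
#' the baseline profile multiply on the odds scale (then convert back to a
#' probability), rate ratios multiply the expected missed work days, and
#' dollar effects add to baseline income. An index-specification effect set
#' applies its per-point ratio to the gap between the profile's index value
#' and the baseline index of 100. In `fitted` mode the fitted models
#' evaluate the profile directly through their linear predictors.
#'
#' @param profile an `msk_profile`.
#' @param effects in published mode, an effects table from
#'   [published_effects()] (the specification is inferred from the presence
#'   of an `index` row); in fitted mode, a named list of `msk_fit` objects
#'   (any subset of the four outcomes).
#' @param baseline a baseline-outcomes list, see [baseline_outcomes()].
#'   Ignored in fitted mode.
#' @param mode `"published"` or `"fitted"`.
#' @param mapping index mapping used when the profile's index value must be
#'   computed from its items.
#' @return A list of class `msk_prediction` with elements `employment`,
#'   `ssi` (probabilities), `income` (2010 dollars) and `missed_days`
#'   (expected days). The print method shows probabilities rounded to whole
#'   percent, as in the worked examples; unrounded values are retained.
#' @export
#' @examples
#' predict_profile(covariate_profile(items = c(walk = 2)),
#'                 published_effects("full"), baseline_outcomes("full"))
predict_profile <- function(profile, effects,
                            baseline = baseline_outcomes(),
                            mode = c("published", "fitted"),
                            mapping = default_index_mapping()) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "msk_profile"))
  if (mode == "fitted") {
    return(predict_profile_fitted(profile, effects, mapping))
  }

  eff <- effects
  is_index_spec <- any(eff$term_type == "index")
  base_profile <- baseline$profile %||% reference_profile()

  lookup <- function(tt, key, level = NA_character_) {
    sel <- eff$term_type == tt & eff$key == key
    if (!is.na(level)) sel <- sel & !is.na(eff$level) & eff$level == level
    row <- eff[sel, , drop = FALSE]
    if (nrow(row) != 1) {
      stop(sprintf("no published effect for %s '%s'%s", tt, key,
                   if (is.na(level)) "" else paste0(" level ", level)),
           call. = FALSE)
    }
    row
  }

  # gather multiplicative/additive contributions per outcome
  or_emp <- 1; or_ssi <- 1; rr_days <- 1; d_income <- 0
  take <- function(row, outcome) {
    v <- row[[outcome]]
    if (is.na(v)) {
      stop(sprintf("published %s effect for %s '%s' is blank", outcome,
                   row$term_type, row$key), call. = FALSE)
    }
    v
  }
  compose <- function(row) {
    or_emp <<- or_emp * take(row, "employment")
    or_ssi <<- or_ssi * take(row, "ssi")
    rr_days <<- rr_days * take(row, "missed_days")
    d_income <<- d_income + take(row, "income")
  }

  for (tt_key in list(c("sex", "male"), c("age", NA), c("year", NA),
                      c("education", NA))) {
    tt <- tt_key[1]
    cur <- switch(tt, sex = profile$sex, age = profile$age_group,
                  year = as.character(profile$year),
                  education = profile$education)
    ref <- switch(tt, sex = base_profile$sex, age = base_profile$age_group,
                  year = as.character(base_profile$year),
                  education = base_profile$education)
    if (!identical(cur, ref)) {
      # compose the profile's level and remove the baseline's, if non-reference
      refs <- c(sex = "female", age = msk_age_levels[1], year = "2010",
                education = msk_education_levels[1])
      if (cur != refs[[tt]]) compose(lookup(tt, cur))
      if (ref != refs[[tt]]) {
        row <- lookup(tt, ref)
        or_emp <- or_emp / take(row, "employment")
        or_ssi <- or_ssi / take(row, "ssi")
        rr_days <- rr_days / take(row, "missed_days")
        d_income <- d_income - take(row, "income")
      }
    }
  }
  if (!identical(profile$occupation, base_profile$occupation) &&
      profile$occupation != "unknown") {
    row <- lookup("occupation", profile$occupation)
    # occupation effects exist only for the employed-population outcomes
    rr_days <- rr_days * take(row, "missed_days")
    d_income <- d_income + take(row, "income")
  }

  item_set <- if (is_index_spec) msk_nonindex_items else msk_items
  for (it in item_set) {
    code <- profile$items[[it]]
    if (code >= 2L) compose(lookup("item", it, as.character(code)))
  }
  for (cs in profile$causes) {
    compose(lookup("cause", cs))
  }
  if (is_index_spec) {
    idx_row <- eff[eff$term_type == "index", , drop = FALSE]
    delta <- profile_index(profile, mapping) - 100
    or_emp <- or_emp * idx_row$employment^delta
    or_ssi <- or_ssi * idx_row$ssi^delta
    rr_days <- rr_days * idx_row$missed_days^delta
    d_income <- d_income + idx_row$income * delta
  }

  structure(list(
    employment = apply_odds_ratio(baseline$employment, or_emp),
    ssi = apply_odds_ratio(baseline$ssi, or_ssi),
    income = baseline$income + d_income,
    missed_days = baseline$missed_days * rr_days,
    mode = "published"), class = "msk_prediction")
}

profile_to_newdata <- function(profile, mapping = default_index_mapping()) {
  nd <- data.frame(
    age_group = factor(profile$age_group, levels = msk_age_levels),
    sex = factor(profile$sex, levels = msk_sex_levels),
    education = factor(profile$education, levels = msk_education_levels),
    occupation = factor(profile$occupation, levels = msk_occupation_levels),
    year_f = factor(as.character(profile$year),
                    levels = c("2010", as.character(2004:2009))),
    pf_index = profile_index(profile, mapping))
  for (it in msk_items) {
    nd[[paste0("lim_", it)]] <- factor(profile$items[[it]], levels = 1:5)
  }
  for (cs in msk_causes) {
    nd[[paste0("cause_", cs)]] <- as.integer(cs %in% profile$causes)
  }
  nd
}

predict_profile_fitted <- function(profile, fits, mapping) {
  if (inherits(fits, "msk_fit")) fits <- list(fits)
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, function(f) f$outcome, character(1))
  }
  nd <- profile_to_newdata(profile, mapping)
  out <- list(employment = NA_real_, ssi = NA_real_, income = NA_real_,
              missed_days = NA_real_, mode = "fitted")
  for (nm in names(fits)) {
    out[[nm]] <- unname(stats::predict(fits[[nm]]$model, newdata = nd,
                                       type = "response"))
  }
  structure(out, class = "msk_prediction")
}

#' @export
print.msk_prediction <- function(x, ...) {
  cat(sprintf("Predicted outcomes (%s effects):\n", x$mode))
  if (!is.na(x$employment)) {
    cat(sprintf("  employment probability: %d%%\n",
                round(100 * x$employment)))
  }
  if (!is.na(x$ssi)) {
    cat(sprintf("  SSI probability:        %d%%\n", round(100 * x$ssi)))
  }
  if (!is.na(x$income)) {
    cat(sprintf("  household income:       $%s\n",
                format(round(x$income), big.mark = ",")))
  }
  if (!is.na(x$missed_days)) {
    cat(sprintf("  missed work days:       %.1f\n", x$missed_days))
  }
  invisible(x)
}
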