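#' Default preprocessing configuration
#'
#' Bundles the survey preparation constants: the eight household income
#' reporting bands with their midpoints (nominal dollars), the CPI deflators
#' used to express 2004-2009 incomes in 2010 dollars, and the missed-work-day
#' cap of 100 days (long absences beyond roughly 100 work days are counted
#' as disability rather than absenteeism).
#'
#' @param params optionally, an `msk_params` object whose income bands and
#'   CPI table should be used, so preprocessing matches the generator.
#' @return A list with components `income_bins` (`edges`, `midpoints`),
#'   `cpi` (named deflators, 2010 = 1) and `cap` (100).
#' @export
default_preprocess_config <- function(params = NULL) {
  if (is.null(params)) params <- default_params()
  list(income_bins = params$income_bins, cpi = params$cpi, cap = 100L)
}

#' Convert an income band to its midpoint in 2010 dollars
#'
#' Household income is reported in one of eight bands; the band midpoint is
#' used as a semi-continuous proxy and deflated to 2010 dollars with the
#' consumer price index (the nominal midpoint is divided by the survey
#' year's deflator).
#'
#' @param band integer band codes, 1-8.
#' @param year survey year(s), present in the configuration's CPI table.
#' @param config a preprocessing configuration, see
#'   [default_preprocess_config()].
#' @return Midpoint income in 2010 dollars.
#' @export
#' @examples
#' income_midpoint(3, 2010)
#' income_midpoint(3, 2004)  # inflated to 2010 dollars
income_midpoint <- function(band, year, config = default_preprocess_config()) {
  if (any(!band %in% 1:8)) {
    stop("unknown income band: bands are coded 1-8", call. = FALSE)
  }
  yr <- as.character(year)
  if (any(!yr %in% names(config$cpi))) {
    stop(sprintf("year %s not present in the CPI deflator table",
                 paste(unique(yr[!yr %in% names(config$cpi)]), collapse = ", ")),
         call. = FALSE)
  }
  unname(config$income_bins$midpoints[band] / config$cpi[yr])
}

#' Cap missed work days
#'
#' Top-codes annual missed work days at the configured cap (default 100),
#' leaving smaller values untouched.
#'
#' @param days non-negative integer day counts (NAs pass through).
#' @param cap the cap, a positive integer.
#' @return `pmin(days, cap)`.
#' @export
#' @examples
#' cap_missed_days(c(0, 40, 250))
cap_missed_days <- function(days, cap = 100L) {
  if (length(cap) != 1 || cap <= 0) stop("cap must be positive", call. = FALSE)
  if (any(days < 0, na.rm = TRUE)) {
    stop("missed work days must be non-negative", call. = FALSE)
  }
  pmin(days, as.integer(cap))
}

#' Expand a cohort into an analysis design
#'
#' Applies the data-preparation rules and produces the regression design for
#' one of the two model specifications:
#' \describe{
#'   \item{full}{each of the eight limitation items is decoupled into four
#'     indicator variables (one per difficulty level, "not at all difficult"
#'     as the reference), alongside cause flags, demographics, survey year
#'     and education (plus occupation in employed-population models).}
#'   \item{index}{the Physical Function Index enters as a single 0-100
#'     covariate, with the sitting, reaching and standing items (which the
#'     index excludes) kept as indicator sets, plus the same controls.}
#' }
#' Preparation adds the index, converts income bands to CPI-adjusted
#' midpoints, and caps missed work days.
#'
#' @param cohort a cohort data frame from [generate_cohort()] or
#'   [read_cohort()].
#' @param specification `"full"` or `"index"`.
#' @param config a preprocessing configuration.
#' @param mapping index mapping passed to [score_index()].
#' @param msk_only if `TRUE`, limitations of respondents without any MSK
#'   cause flag are neutralized (treated as "not at all difficult") before
#'   scoring and design expansion.
#' @return An object of class `msk_design`: a list with the prepared data
#'   (`data`), the `specification`, and the `config`.
#' @export
expand_design <- function(cohort, specification = c("index", "full"),
                          config = default_preprocess_config(),
                          mapping = default_index_mapping(),
                          msk_only = TRUE) {
  specification <- match.arg(specification)
  df <- cohort
  if (isTRUE(msk_only)) {
    has_cause <- Reduce(`|`, lapply(msk_cause_cols,
                                    function(cc) df[[cc]] > 0))
    for (col in msk_item_cols) {
      df[[col]] <- ifelse(has_cause, df[[col]], 1L)
    }
  }
  df <- add_function_index(df, mapping = mapping, msk_only = FALSE)
  for (col in msk_item_cols) {
    df[[col]] <- factor(df[[col]], levels = 1:5)
  }
  df$year_f <- factor(as.character(df$year),
                      levels = c("2010", as.character(2004:2009)))
  emp <- df$employed == 1L
  df$income_mid <- NA_real_
  df$income_mid[emp] <- income_midpoint(df$income_band[emp], df$year[emp],
                                        config)
  df$missed_days[emp] <- cap_missed_days(df$missed_days[emp], config$cap)

  structure(list(data = df, specification = specification, config = config),
            class = "msk_design")
}

# Right-hand-side terms for a specification. Occupation is included only for
# the employed-population outcomes (income, missed days).
design_terms <- function(specification, with_occupation) {
  lims <- if (specification == "full") {
    msk_item_cols
  } else {
    c("pf_index", paste0("lim_", msk_nonindex_items))
  }
  c("sex", "age_group", lims, msk_cause_cols, "year_f", "education",
    if (with_occupation) "occupation")
}

# Population filter per outcome: employment and SSI use all adults; income
# and missed days use the employed population.
design_population <- function(design, outcome) {
  df <- design$data
  if (outcome %in% c("income", "missed_days")) df[df$employed == 1L, ] else df
}

# Collapse limitation-item levels with no observations in the analysis
# population into the adjacent (lower) severity level, with a warning. With
# zero observations this amounts to dropping the empty level, which prevents
# all-zero indicator columns.
merge_empty_levels <- function(df, terms) {
  for (col in intersect(terms, msk_item_cols)) {
    counts <- table(df[[col]])
    empty <- names(counts)[counts == 0]
    if (length(empty)) {
      if (sum(counts > 0) >= 2) {
        warning(sprintf(
          "no observations at level(s) %s of %s in this population; merged into the adjacent severity level",
          paste(empty, collapse = ", "), col), call. = FALSE)
      }
      df[[col]] <- droplevels(df[[col]])
    }
  }
  # unused demographic levels in a small population are dropped quietly
  for (col in intersect(terms, c("age_group", "education", "occupation",
                                 "year_f", "sex"))) {
    df[[col]] <- droplevels(df[[col]])
  }
  df
}

# Terms that actually vary in the analysis population; constant columns
# (single-level factors, zero-variance covariates) carry no information and
# are dropped from the fit.
active_terms <- function(df, terms) {
  keep <- vapply(terms, function(tm) {
    v <- df[[tm]]
    if (is.factor(v)) nlevels(droplevels(v)) >= 2
    else length(unique(v)) >= 2
  }, logical(1))
  terms[keep]
}
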