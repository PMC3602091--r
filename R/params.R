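#' Default generative parameters for the synthetic survey cohort
#'
#' Builds the parameter set that defines the synthetic NHIS-style study
#' population. The four outcome models (employment, SSI receipt, household
#' income, missed work days) use the published index-specification effects as
#' ground truth: odds ratios, dollar coefficients and rate ratios per
#' covariate, with the Physical Function Index entering at 1.02 (employment
#' odds ratio per index point), 0.98 (SSI), $180 (income) and 0.97
#' (missed-days rate ratio). Intercepts that are not published are calibrated
#' in closed form so the reference profile (male, age 60-64, survey year
#' 2010, no high-school degree, occupation unknown, no limitations) attains
#' the published baselines: employment probability 0.61, SSI probability
#' 0.045, and 2.5 expected missed work days.
#'
#' Activity limitations are generated from a person-level latent severity
#' trait with per-item thresholds, calibrated in closed form so the
#' population prevalence of any difficulty on each item matches the published
#' marginal rates (walking 9.6\%, climbing 7.8\%, sitting 7.1\%, reaching
#' 5.7\%, standing 11.7\%, stooping 14.5\%, lifting 6.8\%, pushing 8.95\%).
#'
#' @param seed integer seed stored with the parameters and used by
#'   [generate_cohort()] unless overridden.
#' @return An object of class `msk_params`: a named list with components
#'   `coefs` (per-outcome coefficient sets), `dispersion` (negative-binomial
#'   size parameter theta), `income_sd` (residual standard deviation of
#'   continuous household income, 2010 dollars), `severity` (latent-trait
#'   mixture parameters and per-item thresholds), `marginals` (covariate
#'   distributions), `income_bins` (band edges and midpoints, nominal
#'   dollars), `cpi` (deflators relative to 2010) and `seed`.
#' @export
#' @examples
#' p <- default_params()
#' validate_params(p)
default_params <- function(seed = 1L) {
  or4 <- function(l2, l3, l4, l5) {
    stats::setNames(log(c(l2, l3, l4, l5)), as.character(2:5))
  }
  dollars4 <- function(l2, l3, l4, l5) {
    stats::setNames(c(l2, l3, l4, l5), as.character(2:5))
  }

  age_names  <- msk_age_levels[-1]
  year_names <- as.character(2004:2009)
  edu_names  <- msk_education_levels[-1]
  occ_names  <- msk_occupation_levels[-1]

  coefs <- list(
    employment = list(
      # log-odds scale; intercept calibrated below
      male = log(1.75),
      age = stats::setNames(log(c(1.51, 1.54, 1.39, 0.95, 0.45, 0.16, 0.05)),
                            age_names),
      index = log(1.02),
      items = list(
        sit   = or4(0.94, 0.81, 0.72, 0.50),
        reach = or4(0.84, 0.69, 0.53, 0.46),
        stand = or4(0.75, 0.64, 0.47, 0.29)),
      cause = stats::setNames(log(c(1.09, 1.14, 0.86, 1.20)), msk_causes),
      year = stats::setNames(log(c(1.24, 1.22, 1.20, 1.18, 1.13, 1.04)),
                             year_names),
      education = stats::setNames(log(c(1.45, 1.93, 1.96)), edu_names)),
    ssi = list(
      male = log(0.86),
      age = stats::setNames(log(c(1.47, 1.71, 1.95, 2.15, 2.08, 1.58, 0.77)),
                            age_names),
      index = log(0.98),
      items = list(
        sit   = or4(1.06, 1.32, 1.57, 1.35),
        reach = or4(1.09, 1.21, 1.55, 1.18),
        stand = or4(1.47, 1.65, 2.27, 2.05)),
      cause = stats::setNames(log(c(1.02, 0.94, 1.21, 1.15)), msk_causes),
      year = stats::setNames(log(c(0.86, 0.87, 0.85, 0.95, 0.97, 0.93)),
                             year_names),
      education = stats::setNames(log(c(0.42, 0.24, 0.19)), edu_names)),
    income = list(
      # dollar scale, 2010 dollars; published intercept
      intercept = 4231,
      male = 2175,
      age = stats::setNames(c(7198, 7869, 7889, 7336, 5851, 3709, -1810),
                            age_names),
      index = 180,
      items = list(
        sit   = dollars4(87, 189, 1278, -1323),
        # the published income cell for "can't reach at all" is blank; the
        # generator uses 0 for that level
        reach = dollars4(-361, 37, -1093, 0),
        stand = dollars4(-116, -870, -574, -337)),
      cause = stats::setNames(c(-2116, -1185, -834, -1893), msk_causes),
      year = stats::setNames(c(2302, 2362, 2280, -2616, 2169, 557),
                             year_names),
      education = stats::setNames(c(18262, 37808, 49722), edu_names),
      occupation = stats::setNames(
        c(9017, 7635, 8535, 9342, 1828, -4099, 7877, -1591, 318, 7404,
          -3600, 5142, -6835, -5245, -4045, 2178, 2420, -2843, 342, 4799,
          638, -287, 11409),
        occ_names)),
    missed_days = list(
      # log-rate scale; intercept calibrated below
      male = log(0.73),
      age = stats::setNames(log(c(1.12, 1.10, 1.10, 1.18, 1.11, 1.06, 0.84)),
                            age_names),
      index = log(0.97),
      items = list(
        sit   = or4(1.10, 1.14, 1.23, 1.19),
        reach = or4(1.08, 1.19, 1.11, 2.01),
        stand = or4(1.06, 1.40, 1.23, 1.28)),
      cause = stats::setNames(log(c(1.50, 2.19, 1.69, 1.28)), msk_causes),
      year = stats::setNames(log(c(1.04, 1.12, 1.07, 1.09, 1.04, 1.02)),
                             year_names),
      education = stats::setNames(log(c(1.11, 1.02, 0.97)), edu_names),
      occupation = stats::setNames(
        log(c(1.22, 1.36, 1.56, 1.49, 1.38, 1.74, 1.54, 1.21, 1.28, 1.35,
              1.50, 1.99, 1.26, 1.39, 1.16, 1.30, 1.52, 1.34, 1.66, 1.82,
              1.67, 1.80, 0.93)),
        occ_names))
  )

  # Calibrate unpublished intercepts so the reference profile (male, 60-64,
  # 2010, index = 100, all other covariates at reference) hits the published
  # baseline outcomes.
  ref_lp <- function(cf) cf$male + cf$age[["60-64"]] + 100 * cf$index
  baselines <- list(employment = 0.61, ssi = 0.045, missed_days = 2.5)
  coefs$employment$intercept <-
    stats::qlogis(baselines$employment) - ref_lp(coefs$employment)
  coefs$ssi$intercept <-
    stats::qlogis(baselines$ssi) - ref_lp(coefs$ssi)
  coefs$missed_days$intercept <-
    log(baselines$missed_days) - ref_lp(coefs$missed_days)

  severity <- list(
    p_limited = 0.25,
    # prevalence of any difficulty (code >= 2), per item
    item_prevalence = c(walk = 0.096, climb = 0.078, sit = 0.071,
                        reach = 0.057, stand = 0.117, stoop = 0.145,
                        lift = 0.068, push = 0.0895),
    # among those with any difficulty on an item, share at code >= 3, >= 4, = 5
    severity_shares = c(0.60, 0.35, 0.18),
    sigma_item = 1.0)
  severity$thresholds <- severity_thresholds(severity)

  marginals <- list(
    age = stats::setNames(
      c(0.38, 0.09, 0.09, 0.09, 0.08, 0.07, 0.06, 0.14), msk_age_levels),
    male = 0.45,
    education = stats::setNames(c(0.13, 0.55, 0.20, 0.12),
                                msk_education_levels),
    occupation = stats::setNames(
      c(0.05, 0.09, 0.04, 0.03, 0.02, 0.01, 0.02, 0.01, 0.06, 0.02, 0.05,
        0.03, 0.02, 0.05, 0.04, 0.03, 0.10, 0.11, 0.01, 0.06, 0.04, 0.05,
        0.05, 0.01),
      msk_occupation_levels),
    year = stats::setNames(rep(1 / 7, 7), as.character(msk_years)),
    # primary attributed cause among limited respondents, plus the chance of
    # each additional cause being flagged as well
    cause_primary = c(back = 0.40, injury = 0.12, msk = 0.18,
                      arthritis = 0.30),
    cause_secondary = 0.15)

  structure(list(
    coefs = coefs,
    baselines = baselines,
    # negative-binomial size (theta), calibrated so about 0.5% of the
    # employed population reports more than 100 missed work days
    dispersion = 1.5,
    income_sd = 16000,
    severity = severity,
    marginals = marginals,
    income_bins = list(
      edges = c(0, 10000, 20000, 30000, 40000, 55000, 75000, 110000, Inf),
      midpoints = c(5000, 15000, 25000, 35000, 47500, 65000, 92500, 150000)),
    cpi = stats::setNames(
      c(0.866, 0.896, 0.925, 0.951, 0.987, 0.984, 1.000),
      as.character(msk_years)),
    seed = as.integer(seed)
  ), class = "msk_params")
}

# Closed-form latent-trait thresholds. Each limited respondent draws a
# standard-normal severity s; item latents are s + N(0, sigma_item^2). The
# threshold for code >= k on item j places P(latent > c_jk | limited) at the
# calibrated share of the item's target prevalence.
severity_thresholds <- function(severity) {
  p <- severity$item_prevalence
  pi0 <- severity$p_limited
  if (pi0 <= 0) {
    th <- matrix(Inf, length(p), 4,
                 dimnames = list(names(p), paste0("ge", 2:5)))
    return(th)
  }
  if (any(p / pi0 > 1)) {
    stop("p_limited is smaller than an item prevalence target", call. = FALSE)
  }
  shares <- c(1, severity$severity_shares)     # code >= 2, 3, 4, 5
  s_tot <- sqrt(1 + severity$sigma_item^2)
  th <- sapply(seq_along(shares), function(k) {
    stats::qnorm(1 - shares[k] * p / pi0) * s_tot
  })
  rownames(th) <- names(p)
  colnames(th) <- paste0("ge", 2:5)
  th
}

#' Validate generative parameters
#'
#' Checks the structural invariants of an `msk_params` object and fails with
#' an error naming the offending field.
#'
#' @param params an `msk_params` object, as returned by [default_params()].
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid params: %s %s", field, msg), call. = FALSE)
  }
  if (!inherits(params, "msk_params")) fail("object", "is not 'msk_params'")

  m <- params$marginals
  for (nm in c("age", "education", "occupation", "year")) {
    if (abs(sum(m[[nm]]) - 1) > 1e-9) {
      fail(paste0("marginals$", nm), "probabilities do not sum to 1")
    }
    if (any(m[[nm]] < 0)) fail(paste0("marginals$", nm), "has negative mass")
  }
  if (m$male < 0 || m$male > 1) fail("marginals$male", "not in [0,1]")
  if (abs(sum(m$cause_primary) - 1) > 1e-9) {
    fail("marginals$cause_primary", "probabilities do not sum to 1")
  }

  edges <- params$income_bins$edges
  if (length(edges) != 9) fail("income_bins$edges", "must define exactly 8 bins")
  if (any(diff(edges) <= 0)) fail("income_bins$edges", "not strictly increasing")
  mid <- params$income_bins$midpoints
  if (length(mid) != 8) fail("income_bins$midpoints", "must have 8 entries")
  if (any(mid < edges[-9] | mid >= edges[-1])) {
    fail("income_bins$midpoints", "must lie inside their bins")
  }

  if (!is.numeric(params$dispersion) || params$dispersion <= 0) {
    fail("dispersion", "must be > 0")
  }
  if (params$income_sd <= 0) fail("income_sd", "must be > 0")
  sv <- params$severity
  if (sv$p_limited < 0 || sv$p_limited > 1) fail("severity$p_limited", "not in [0,1]")
  if (sv$p_limited > 0 && any(sv$item_prevalence / sv$p_limited > 1)) {
    fail("severity$p_limited", "smaller than an item prevalence target")
  }
  if (any(diff(sv$severity_shares) >= 0) || any(sv$severity_shares >= 1)) {
    fail("severity$severity_shares", "must be decreasing shares in (0,1)")
  }
  if (any(params$cpi <= 0)) fail("cpi", "deflators must be positive")

  # every covariate slot present for every outcome model
  for (oc in msk_outcomes) {
    cf <- params$coefs[[oc]]
    if (is.null(cf)) fail(paste0("coefs$", oc), "missing")
    for (slot in c("intercept", "male", "age", "index", "items", "cause",
                   "year", "education")) {
      if (is.null(cf[[slot]])) fail(paste0("coefs$", oc, "$", slot), "missing")
    }
    if (length(cf$age) != 7) fail(paste0("coefs$", oc, "$age"), "needs 7 levels")
    for (it in msk_nonindex_items) {
      if (length(cf$items[[it]]) != 4) {
        fail(paste0("coefs$", oc, "$items$", it), "needs 4 levels")
      }
    }
    if (oc %in% c("income", "missed_days") &&
        length(cf$occupation) != length(msk_occupation_levels) - 1) {
      fail(paste0("coefs$", oc, "$occupation"), "needs 23 levels")
    }
  }
  invisible(params)
}

#' Read and write generative parameters as YAML
#'
#' `write_params()` serializes an `msk_params` object to a YAML file;
#' `read_params()` restores it (recomputing the derived latent-trait
#' thresholds) and validates the result.
#'
#' @param params an `msk_params` object.
#' @param path file path.
#' @return `read_params()` returns a validated `msk_params` object.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  x$severity$thresholds <- NULL  # derived; recomputed on read
  # named vectors become YAML maps (plain vectors would lose their names)
  listify <- function(v) {
    if (is.list(v)) lapply(v, listify)
    else if (!is.null(names(v))) as.list(v)
    else v
  }
  x <- listify(x)
  x$income_bins$edges <- ifelse(is.infinite(x$income_bins$edges),
                                ".inf", x$income_bins$edges)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  relist_named <- function(l) if (is.list(l)) unlist(l) else l
  for (oc in names(x$coefs)) {
    for (slot in c("age", "cause", "year", "education", "occupation")) {
      if (!is.null(x$coefs[[oc]][[slot]])) {
        x$coefs[[oc]][[slot]] <- relist_named(x$coefs[[oc]][[slot]])
      }
    }
    x$coefs[[oc]]$items <- lapply(x$coefs[[oc]]$items, relist_named)
  }
  for (slot in c("item_prevalence", "severity_shares")) {
    x$severity[[slot]] <- relist_named(x$severity[[slot]])
  }
  for (slot in c("age", "education", "occupation", "year", "cause_primary")) {
    x$marginals[[slot]] <- relist_named(x$marginals[[slot]])
  }
  x$cpi <- relist_named(x$cpi)
  x$income_bins$edges <- as.numeric(ifelse(x$income_bins$edges == ".inf",
                                           Inf, x$income_bins$edges))
  x$income_bins$midpoints <- as.numeric(x$income_bins$midpoints)
  x$severity$thresholds <- severity_thresholds(x$severity)
  params <- structure(x, class = "msk_params")
  validate_params(params)
  params
}
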