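# Synthetic survey cohort generation.
#
# Limitation items come from a shared latent severity trait: a respondent is
# "limited" with probability p_limited; limited respondents draw a standard
# normal severity s, and item j's latent value is s + N(0, sigma_item^2),
# cut at per-item thresholds into codes 1-5. The shared trait induces the
# positive inter-item correlation seen in real survey data, where the same
# person typically reports several limitations at once. Outcomes are then
# drawn from the four index-specification models applied to each person's
# covariates.

local_seed <- function(seed) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }
}

#' Generate a synthetic survey cohort
#'
#' Draws `n` respondents with demographics, eight 5-level activity-limitation
#' items with musculoskeletal cause flags, and four economic outcomes
#' (employment, SSI receipt, banded household income, annual missed work
#' days), all generated from the models encoded in `params`. Employment and
#' SSI are Bernoulli draws on the logistic scale; household income is drawn
#' as a continuous linear-model value plus Gaussian noise, floored at zero,
#' converted to nominal dollars with the year's CPI deflator and then binned
#' into the eight reporting bands; missed work days are negative-binomial
#' with a log link. Income band and missed days are recorded only for
#' employed respondents.
#'
#' @param params an `msk_params` object, see [default_params()].
#' @param n number of respondents (>= 1).
#' @param seed integer seed; defaults to `params$seed`. Generation is fully
#'   reproducible given the seed and does not disturb the caller's random
#'   number stream.
#' @return A data frame with one row per respondent and columns `id`,
#'   `age_group`, `sex`, `education`, `occupation`, `year`, `lim_walk` ...
#'   `lim_push` (codes 1-5), `cause_back`, `cause_injury`, `cause_msk`,
#'   `cause_arthritis` (0/1), `employed`, `ssi` (0/1), `income_band` (1-8,
#'   employed only), `missed_days` (employed only).
#' @export
#' @examples
#' cohort <- generate_cohort(default_params(), n = 500, seed = 42)
#' table(cohort$lim_walk)
generate_cohort <- function(params, n, seed = params$seed) {
  validate_params(params)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  restore <- local_seed(seed)
  on.exit(restore())

  m <- params$marginals
  df <- data.frame(
    id = seq_len(n),
    age_group = factor(sample(msk_age_levels, n, TRUE, m$age),
                       levels = msk_age_levels),
    sex = factor(ifelse(stats::runif(n) < m$male, "male", "female"),
                 levels = msk_sex_levels),
    education = factor(sample(msk_education_levels, n, TRUE, m$education),
                       levels = msk_education_levels),
    occupation = factor(rep("unknown", n), levels = msk_occupation_levels),
    year = as.integer(sample(as.character(msk_years), n, TRUE, m$year)),
    stringsAsFactors = FALSE)

  # latent-trait limitation items
  th <- severity_thresholds(params$severity)
  limited <- stats::runif(n) < params$severity$p_limited
  s <- stats::rnorm(n)
  for (it in msk_items) {
    latent <- s + stats::rnorm(n, sd = params$severity$sigma_item)
    code <- 1L + findInterval(latent, th[it, ])
    code[!limited] <- 1L
    df[[paste0("lim_", it)]] <- code
  }

  # cause attribution: every limited respondent gets a primary MSK cause,
  # plus independent chances of additional causes; the unlimited get none
  primary <- sample(msk_causes, n, TRUE, m$cause_primary[msk_causes])
  for (cs in msk_causes) {
    flag <- limited & (primary == cs |
                         stats::runif(n) < m$cause_secondary)
    df[[paste0("cause_", cs)]] <- as.integer(flag)
  }

  idx <- add_function_index(df)

  p_emp <- stats::plogis(true_linear_predictor(params, idx, "employment"))
  df$employed <- as.integer(stats::rbinom(n, 1L, p_emp))
  p_ssi <- stats::plogis(true_linear_predictor(params, idx, "ssi"))
  df$ssi <- as.integer(stats::rbinom(n, 1L, p_ssi))

  emp <- df$employed == 1L
  n_emp <- sum(emp)
  df$occupation[emp] <- factor(
    sample(msk_occupation_levels, n_emp, TRUE, m$occupation),
    levels = msk_occupation_levels)
  idx$occupation <- df$occupation

  df$income_band <- NA_integer_
  df$missed_days <- NA_integer_
  if (n_emp > 0) {
    lp_inc <- true_linear_predictor(params, idx, "income")[emp]
    income_2010 <- pmax(lp_inc + stats::rnorm(n_emp, sd = params$income_sd), 0)
    nominal <- income_2010 * params$cpi[as.character(df$year[emp])]
    df$income_band[emp] <- findInterval(nominal, params$income_bins$edges,
                                        rightmost.closed = FALSE)
    mu <- exp(true_linear_predictor(params, idx, "missed_days")[emp])
    df$missed_days[emp] <- as.integer(pmin(
      stats::rnbinom(n_emp, size = params$dispersion, mu = mu), 365L))
  }
  df
}

#' Evaluate the generative linear predictor for an outcome
#'
#' Computes the true (generative) linear predictor of one of the four
#' outcome models for every row of a cohort, on the model's link scale
#' (log-odds for employment and SSI, dollars for income, log rate for missed
#' days). Used by the generator itself and by parameter-recovery and
#' self-consistency checks.
#'
#' @param params an `msk_params` object.
#' @param cohort a cohort data frame; if the `pf_index` column is absent it
#'   is computed with the default index mapping.
#' @param outcome one of `"employment"`, `"ssi"`, `"income"`,
#'   `"missed_days"`.
#' @return A numeric vector of linear-predictor values.
#' @export
true_linear_predictor <- function(params, cohort, outcome) {
  outcome <- match.arg(outcome, msk_outcomes)
  cf <- params$coefs[[outcome]]
  if (is.null(cohort$pf_index)) cohort <- add_function_index(cohort)

  pad <- function(v, ref) c(stats::setNames(0, ref), v)
  age_v <- pad(cf$age, msk_age_levels[1])
  year_v <- pad(cf$year, "2010")
  edu_v <- pad(cf$education, msk_education_levels[1])

  lp <- cf$intercept +
    cf$male * (cohort$sex == "male") +
    unname(age_v[as.character(cohort$age_group)]) +
    cf$index * cohort$pf_index +
    unname(year_v[as.character(cohort$year)]) +
    unname(edu_v[as.character(cohort$education)])
  for (it in msk_nonindex_items) {
    item_v <- c(0, cf$items[[it]])
    lp <- lp + unname(item_v[cohort[[paste0("lim_", it)]]])
  }
  for (cs in msk_causes) {
    lp <- lp + cf$cause[[cs]] * cohort[[paste0("cause_", cs)]]
  }
  if (!is.null(cf$occupation)) {
    occ_v <- pad(cf$occupation, "unknown")
    lp <- lp + unname(occ_v[as.character(cohort$occupation)])
  }
  lp
}

#' Write and read cohort tables
#'
#' `write_cohort()` stores a cohort as plain CSV; `read_cohort()` parses it
#' back, restoring the canonical factor levels and validating required
#' columns and code ranges. The round trip is lossless.
#'
#' @param cohort a cohort data frame from [generate_cohort()].
#' @param path a CSV file path.
#' @return `read_cohort()` returns a validated cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("age_group", "sex", "education", "occupation"))))
  missing_cols <- setdiff(msk_cohort_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("cohort file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in msk_item_cols) {
    bad <- which(!(df[[col]] %in% 1:5))
    if (length(bad)) {
      stop(sprintf("invalid limitation code in column '%s' at row %d",
                   col, bad[1]), call. = FALSE)
    }
  }
  lv <- list(age_group = msk_age_levels, sex = msk_sex_levels,
             education = msk_education_levels,
             occupation = msk_occupation_levels)
  for (col in names(lv)) {
    bad <- which(!(df[[col]] %in% lv[[col]]))
    if (length(bad)) {
      stop(sprintf("unknown level in column '%s' at row %d", col, bad[1]),
           call. = FALSE)
    }
    df[[col]] <- factor(df[[col]], levels = lv[[col]])
  }
  emp <- df$employed == 1L
  if (any(!emp & (!is.na(df$income_band) | !is.na(df$missed_days)))) {
    bad <- which(!emp & (!is.na(df$income_band) | !is.na(df$missed_days)))[1]
    stop(sprintf("income_band/missed_days present for non-employed row %d",
                 bad), call. = FALSE)
  }
  df[, msk_cohort_columns]
}
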