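test_that("logistic fit on a 2x2 table equals the cross-product odds ratio", {
  # degenerate cohort: everyone identical except sex and employment, so the
  # fitted model reduces to the 2x2 table (constant covariates are dropped)
  co <- degenerate_2x2_cohort(f0 = 40, f1 = 25, m0 = 15, m1 = 35)
  fit <- fit_logistic(expand_design(co, "full"), "employment")
  or_fit <- fit$table$exp_estimate[fit$table$term == "sexmale"]
  or_closed <- (35 / 15) / (25 / 40)  # ad/bc from the 2x2 cells
  expect_equal(or_fit, or_closed, tolerance = 1e-8)
})

test_that("null limitation effects are recovered as null", {
  p <- null_limitation_params("employment")
  covered <- 0L; total <- 0L
  for (s in 1:3) {
    co <- generate_cohort(p, 30000, seed = 100 + s)
    f <- suppressWarnings(fit_logistic(expand_design(co, "full"),
                                       "employment"))
    tb <- f$table[grepl("^lim_|^cause_", f$table$term), ]
    ci_lo <- tb$estimate - 1.96 * tb$se
    ci_hi <- tb$estimate + 1.96 * tb$se
    covered <- covered + sum(ci_lo <= 0 & ci_hi >= 0)
    total <- total + nrow(tb)
  }
  expect_gte(covered / total, 0.9)
})

test_that("noise-free income generation recovers the slope exactly", {
  p <- default_params()
  co <- test_cohort(n = 8000, seed = 17)
  emp <- co[co$employed == 1L, ]
  d <- expand_design(emp, "index")
  # replace the banded income with the exact generative value: no noise,
  # no banding -> least squares must return the truth to machine precision
  d$data$income_mid <- true_linear_predictor(p, emp, "income")
  fit <- suppressWarnings(fit_income(d))
  tb <- fit$table
  expect_equal(tb$estimate[tb$term == "pf_index"], 180, tolerance = 1e-8)

  # shifting all incomes moves only the intercept
  d2 <- d
  d2$data$income_mid <- d$data$income_mid + 5000
  fit2 <- suppressWarnings(fit_income(d2))
  tb2 <- fit2$table
  expect_equal(tb2$estimate[tb2$term == "(Intercept)"],
               tb$estimate[tb$term == "(Intercept)"] + 5000,
               tolerance = 1e-6)
  expect_equal(tb2$estimate[tb2$term != "(Intercept)"],
               tb$estimate[tb$term != "(Intercept)"], tolerance = 1e-6)
})

test_that("rank-deficient income designs fail naming the aliased column", {
  co <- test_cohort(n = 4000, seed = 19)
  # force education to be a function of sex: perfectly collinear dummies
  co$education <- factor(ifelse(co$sex == "male", "hs", "no_hs"),
                         levels = levels(co$education))
  d <- expand_design(co, "index")
  expect_error(suppressWarnings(fit_income(d)), "aliased.*education")
})

test_that("doubling the sample shrinks the index SE roughly as 1/sqrt(2)", {
  p <- default_params()
  co <- generate_cohort(p, 60000, seed = 23)
  d_half <- expand_design(co[1:30000, ], "index")
  d_full <- expand_design(co, "index")
  se_half <- with(suppressWarnings(fit_logistic(d_half, "employment"))$table,
                  se[term == "pf_index"])
  se_full <- with(suppressWarnings(fit_logistic(d_full, "employment"))$table,
                  se[term == "pf_index"])
  expect_equal(se_full / se_half, 1 / sqrt(2), tolerance = 0.15)
})

test_that("negative-binomial fit nests the Poisson limit", {
  co <- test_cohort(n = 12000, seed = 29)
  emp <- co[co$employed == 1L, ]
  d <- expand_design(emp, "index")
  p <- default_params()
  mu <- exp(true_linear_predictor(p, emp, "missed_days"))
  set.seed(31)
  d$data$missed_days <- rpois(nrow(d$data), mu)  # Poisson-generated counts
  fit <- suppressWarnings(fit_missed_days(d))
  expect_lt(fit$dispersion, 0.05)  # 1/theta near zero
})

test_that("the fitted intercept satisfies its ML score equation", {
  co <- test_cohort(n = 12000, seed = 29)
  emp <- co[co$employed == 1L, ]
  d <- expand_design(emp, "index")
  fit <- suppressWarnings(fit_missed_days(d))
  # quadratic-variance NB score for the intercept: weighted residuals
  # sum(y - mu) / (1 + mu / theta) vanish at the ML solution
  y <- d$data$missed_days[d$data$employed == 1L]
  mu <- fitted(fit$model)
  score <- sum((y - mu) / (1 + mu / fit$theta))
  expect_lt(abs(score) / sum(abs(y)), 1e-6)
})

test_that("specification comparison moves all outcomes the same way", {
  co <- test_cohort(n = 60000, seed = 37)
  cmp <- suppressWarnings(compare_specifications(co))
  ch <- cmp$outcome_changes
  for (oc in unique(ch$outcome)) {
    sub <- ch$change[ch$outcome == oc]
    expect_true(all(sign(sub) == sign(sub[1])), info = oc)
  }
  # improving function raises employment and income, lowers SSI and absence
  expect_true(all(ch$change[ch$outcome == "employment"] > 0))
  expect_true(all(ch$change[ch$outcome == "income"] > 0))
  expect_true(all(ch$change[ch$outcome == "ssi"] < 0))
  expect_true(all(ch$change[ch$outcome == "missed_days"] < 0))
})

test_that("a null-effect cohort shows no participation change", {
  p <- null_limitation_params("employment")
  co <- generate_cohort(p, 40000, seed = 41)
  cmp <- suppressWarnings(
    compare_specifications(co, outcomes = "employment"))
  expect_lt(max(abs(cmp$participation$change_pp)), 0.15)
})

test_that("recoding someone already at 'somewhat difficult' changes nothing", {
  co <- test_cohort(n = 2000, seed = 43)
  at3 <- co$lim_walk == 3L
  improved <- co
  for (it in c("walk", "climb", "stoop")) {
    col <- paste0("lim_", it)
    sel <- improved[[col]] %in% c(4L, 5L)
    improved[[col]][sel] <- 3L
  }
  expect_identical(improved$lim_walk[at3], co$lim_walk[at3])
})
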