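test_that("odds-ratio transform matches the worked walking example", {
  expect_equal(apply_odds_ratio(0.61, 0.84), 0.84 * (0.61 / 0.39) /
                 (1 + 0.84 * 0.61 / 0.39), tolerance = 1e-12)
  expect_equal(round(100 * apply_odds_ratio(0.61, 0.84)), 57)
  expect_equal(round(100 * apply_odds_ratio(0.61, 0.57)), 47)
  expect_equal(apply_odds_ratio(0.3, 1), 0.3)
})

test_that("odds-ratio application composes multiplicatively and is monotone", {
  set.seed(2)
  p0 <- runif(50, 0.02, 0.98)
  a <- exp(runif(50, -1, 1))
  b <- exp(runif(50, -1, 1))
  expect_equal(apply_odds_ratio(apply_odds_ratio(p0, a), b),
               apply_odds_ratio(p0, a * b), tolerance = 1e-12)
  # inverse returns the starting probability
  expect_equal(apply_odds_ratio(apply_odds_ratio(p0, a), 1 / a), p0,
               tolerance = 1e-12)
  # monotone in both arguments
  expect_true(all(apply_odds_ratio(p0, a * 1.1) > apply_odds_ratio(p0, a)))
  expect_true(all(apply_odds_ratio(pmin(p0 + 0.01, 0.99), a) >
                    apply_odds_ratio(p0, a)))
  expect_error(apply_odds_ratio(1.2, 0.5), "probability")
  expect_error(apply_odds_ratio(0.5, -1), "positive")
})

test_that("published walking effects reproduce the employment sequence", {
  eff <- published_effects("full")
  base <- baseline_outcomes("full")
  got <- sapply(2:5, function(k) {
    pr <- predict_profile(covariate_profile(items = c(walk = k)), eff, base)
    round(100 * pr$employment)
  })
  expect_equal(got, c(57, 55, 52, 47))
  # odds declines implied by the printed odds ratios
  ors <- eff$employment[eff$term_type == "item" & eff$key == "walk"]
  declines <- round(100 * (1 - ors))
  expect_equal(declines[1], 16)
  expect_true(declines[4] %in% c(43, 44))
})

test_that("the reference profile leaves baseline outcomes unchanged", {
  base <- baseline_outcomes("full")
  pr <- predict_profile(reference_profile(), published_effects("full"), base)
  expect_equal(pr$employment, base$employment)
  expect_equal(pr$ssi, base$ssi)
  expect_equal(pr$income, base$income)
  expect_equal(pr$missed_days, base$missed_days)
})

test_that("joint-replacement candidate presets bracket the published range", {
  p3 <- combined_limitation_profile("tkr_candidate_somewhat")
  expect_true(all(p3$items[c("walk", "climb", "sit", "stand", "stoop",
                             "lift", "push")] == 3L))
  expect_identical(p3$items[["reach"]], 1L)
  p4 <- combined_limitation_profile("tkr_candidate_very")
  expect_true(all(p4$items[c("walk", "climb", "sit", "stand", "stoop",
                             "lift", "push")] == 4L))
  expect_error(combined_limitation_profile("thr_candidate"), "arg")

  eff <- published_effects("full")
  base <- baseline_outcomes("full")
  hi <- 100 * predict_profile(p3, eff, base)$employment
  lo <- 100 * predict_profile(p4, eff, base)$employment
  expect_lt(lo, 21)  # the preset pair brackets the published 21-25% range
  expect_gt(hi, 25)
  # the severe preset floors the index
  expect_equal(mskecon:::profile_index(p4), 100 / 3, tolerance = 1e-10)
})

test_that("published and fitted modes agree when coefficients coincide", {
  co <- test_cohort(n = 15000, seed = 47)
  d <- expand_design(co, "index")
  fits <- list(employment = suppressWarnings(fit_logistic(d, "employment")),
               ssi = suppressWarnings(fit_logistic(d, "ssi")))

  # build a published-style effects table from the fitted coefficients
  eff <- fitted_effects_table(fits)
  # baseline = the fitted prediction for the reference profile
  ref <- reference_profile()
  fitted_base <- predict_profile(ref, fits, mode = "fitted")
  base <- list(employment = fitted_base$employment, ssi = fitted_base$ssi,
               income = 0, missed_days = 1, profile = ref)

  profile <- covariate_profile(age_group = "50-54", sex = "female",
                               education = "baccalaureate", year = 2006,
                               items = c(walk = 4, sit = 3, stand = 2),
                               causes = "back")
  pub <- predict_profile(profile, eff, base, mode = "published")
  fit <- predict_profile(profile, fits, mode = "fitted")
  expect_equal(pub$employment, fit$employment, tolerance = 1e-6)
  expect_equal(pub$ssi, fit$ssi, tolerance = 1e-6)
})

test_that("a profile level without a published effect fails by name", {
  eff <- published_effects("full")
  base <- baseline_outcomes("full")
  # the source table's income cell for the worst reaching level is blank
  expect_error(
    predict_profile(covariate_profile(items = c(reach = 5)), eff, base),
    "reach")
  eff2 <- eff[!(eff$term_type == "item" & eff$key == "walk" &
                  eff$level == "3"), ]
  expect_error(
    predict_profile(covariate_profile(items = c(walk = 3)), eff2, base),
    "walk")
})
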