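test_that("generation is reproducible and leaves the RNG stream alone", {
  p <- default_params()
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  a <- generate_cohort(p, 2000, seed = 5)
  after <- rnorm(1)
  b <- generate_cohort(p, 2000, seed = 5)
  expect_identical(a, b)
  expect_identical(before, after)  # caller's stream restored
  c <- generate_cohort(p, 2000, seed = 6)
  expect_false(identical(a, c))
})

test_that("a zero mixing proportion yields a fully unlimited cohort", {
  p <- default_params()
  p$severity$p_limited <- 0
  co <- generate_cohort(p, 1000, seed = 1)
  for (col in paste0("lim_", c("walk", "climb", "sit", "reach", "stand",
                               "stoop", "lift", "push"))) {
    expect_true(all(co[[col]] == 1L), info = col)
  }
  for (col in c("cause_back", "cause_injury", "cause_msk",
                "cause_arthritis")) {
    expect_true(all(co[[col]] == 0L), info = col)
  }
})

test_that("default parameters reproduce the published limitation prevalences", {
  co <- cached("cohort_200k", generate_cohort(default_params(), 2e5, seed = 1))
  targets <- c(walk = 9.6, climb = 7.8, sit = 7.1, reach = 5.7,
               stand = 11.7, stoop = 14.5, lift = 6.8, push = 8.95)
  for (it in names(targets)) {
    prev <- 100 * mean(co[[paste0("lim_", it)]] >= 2)
    expect_lt(abs(prev - targets[[it]]), 1, label = paste("prevalence", it))
  }
  # walking difficulty, the headline figure, within half a point
  expect_lt(abs(100 * mean(co$lim_walk >= 2) - 9.6), 0.5)
})

test_that("cohort respects its structural invariants", {
  co <- test_cohort()
  emp <- co$employed == 1L
  expect_true(all(co$missed_days[emp] <= 365))
  expect_true(all(is.na(co$income_band[!emp])))
  expect_true(all(is.na(co$missed_days[!emp])))
  expect_true(all(co$income_band[emp] %in% 1:8))
  # no MSK cause implies no limitation in this generator
  no_cause <- co$cause_back + co$cause_injury + co$cause_msk +
    co$cause_arthritis == 0
  lim_any <- Reduce(`|`, lapply(paste0("lim_", c("walk", "climb", "sit",
                                                 "reach", "stand", "stoop",
                                                 "lift", "push")),
                                function(c) co[[c]] >= 2))
  expect_false(any(no_cause & lim_any))
})

test_that("raising limitation prevalence never lowers per-item difficulty counts", {
  # common random numbers: identical seed, scaled-up prevalence targets
  p1 <- default_params()
  p2 <- default_params()
  p2$severity$item_prevalence <- p2$severity$item_prevalence * 1.2
  a <- generate_cohort(p1, 20000, seed = 4)
  b <- generate_cohort(p2, 20000, seed = 4)
  for (it in c("walk", "climb", "sit", "reach", "stand", "stoop", "lift",
               "push")) {
    col <- paste0("lim_", it)
    expect_gte(sum(b[[col]] >= 2), sum(a[[col]] >= 2))
    # item-level monotonicity holds row by row under common randomness
    expect_true(all(b[[col]] >= a[[col]]), info = col)
  }
})

test_that("stratum means of missed days match the generative rate", {
  co <- cached("cohort_200k", generate_cohort(default_params(), 2e5, seed = 1))
  p <- default_params()
  emp <- co$employed == 1L
  mu <- exp(true_linear_predictor(p, co, "missed_days"))
  # unlimited employed high-school stratum: big cell, direct formula oracle
  sel <- emp & co$lim_walk == 1L & co$education == "hs"
  mc_se <- sqrt(sum(mu[sel] + mu[sel]^2 / p$dispersion)) / sum(sel)
  expect_lt(abs(mean(co$missed_days[sel]) - mean(mu[sel])), 4 * mc_se)
})

test_that("cohort tables survive a CSV round trip", {
  co <- generate_cohort(default_params(), 1500, seed = 9)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co)
})

test_that("malformed cohort files fail with a precise message", {
  co <- generate_cohort(default_params(), 50, seed = 2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))

  write_cohort(co[, setdiff(names(co), "lim_walk")], path)
  expect_error(read_cohort(path), "lim_walk")

  bad <- co
  bad$lim_climb[17] <- 7L
  write_cohort(bad, path)
  expect_error(read_cohort(path), "lim_climb.*row 17")

  bad <- co
  bad$employed[3] <- 0L
  bad$income_band[3] <- 4L
  write_cohort(bad, path)
  expect_error(read_cohort(path), "row 3")
})
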