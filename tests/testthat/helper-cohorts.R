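# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a mid-sized default cohort for structural tests
test_cohort <- function(n = 20000, seed = 11) {
  cached(sprintf("cohort_%d_%d", n, seed),
         generate_cohort(default_params(), n = n, seed = seed))
}

# the true (generative) coefficient values arranged by fitted term name
truth_vector <- function(params, outcome, terms) {
  cf <- params$coefs[[outcome]]
  v <- stats::setNames(rep(NA_real_, length(terms)), terms)
  v["(Intercept)"] <- cf$intercept
  v["sexmale"] <- cf$male
  for (a in names(cf$age)) v[paste0("age_group", a)] <- cf$age[[a]]
  if ("pf_index" %in% terms) v["pf_index"] <- cf$index
  for (it in names(cf$items)) {
    for (k in 2:5) {
      t <- paste0("lim_", it, k)
      if (t %in% terms) v[t] <- cf$items[[it]][[as.character(k)]]
    }
  }
  for (cs in names(cf$cause)) v[paste0("cause_", cs)] <- cf$cause[[cs]]
  for (y in names(cf$year)) v[paste0("year_f", y)] <- cf$year[[y]]
  for (e in names(cf$education)) v[paste0("education", e)] <- cf$education[[e]]
  if (!is.null(cf$occupation)) {
    for (o in names(cf$occupation)) {
      v[paste0("occupation", o)] <- cf$occupation[[o]]
    }
  }
  v[terms]
}

# params with every limitation-related effect (index, sit/reach/stand,
# causes) zeroed for one outcome, used for null-recovery checks
null_limitation_params <- function(outcome = "employment") {
  p <- default_params()
  cf <- p$coefs[[outcome]]
  cf$index <- 0
  cf$items <- lapply(cf$items, function(x) x * 0)
  cf$cause <- cf$cause * 0
  p$coefs[[outcome]] <- cf
  p
}
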