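# A cohort that is constant in everything except sex and employment, so a
# logistic employment fit reduces to the 2x2 table.
degenerate_2x2_cohort <- function(f0 = 40, f1 = 25, m0 = 15, m1 = 35) {
  co <- generate_cohort(default_params(), f0 + f1 + m0 + m1, seed = 1)
  co$age_group <- factor("45-49", levels = levels(co$age_group))
  co$education <- factor("hs", levels = levels(co$education))
  co$year <- 2010L
  for (col in grep("^lim_", names(co), value = TRUE)) co[[col]] <- 1L
  for (col in grep("^cause_", names(co), value = TRUE)) co[[col]] <- 0L
  co$sex <- factor(rep(c("female", "male"), c(f0 + f1, m0 + m1)),
                   levels = c("female", "male"))
  co$employed <- c(rep(0:1, c(f0, f1)), rep(0:1, c(m0, m1)))
  co$ssi <- 0L
  co$income_band <- ifelse(co$employed == 1L, 3L, NA_integer_)
  co$missed_days <- ifelse(co$employed == 1L, 2L, NA_integer_)
  co
}

# Rewrite an index-specification published-effects table so its employment
# and SSI columns carry the coefficients of the supplied fitted models.
fitted_effects_table <- function(fits) {
  eff <- published_effects("index")
  for (oc in names(fits)) {
    tb <- fits[[oc]]$table
    pull <- function(term) {
      v <- tb$estimate[tb$term == term]
      if (!length(v)) stop("term not in fit: ", term)
      exp(v)
    }
    eff[[oc]][eff$term_type == "sex"] <- pull("sexmale")
    for (a in eff$key[eff$term_type == "age"]) {
      eff[[oc]][eff$term_type == "age" & eff$key == a] <-
        pull(paste0("age_group", a))
    }
    eff[[oc]][eff$term_type == "index"] <- pull("pf_index")
    for (it in c("sit", "reach", "stand")) {
      for (k in 2:5) {
        eff[[oc]][eff$term_type == "item" & eff$key == it &
                    eff$level == k] <- pull(paste0("lim_", it, k))
      }
    }
    for (cs in c("back", "injury", "msk", "arthritis")) {
      eff[[oc]][eff$term_type == "cause" & eff$key == cs] <-
        pull(paste0("cause_", cs))
    }
    for (y in 2004:2009) {
      eff[[oc]][eff$term_type == "year" & eff$key == y] <-
        pull(paste0("year_f", y))
    }
    for (e in c("hs", "baccalaureate", "post_baccalaureate")) {
      eff[[oc]][eff$term_type == "education" & eff$key == e] <-
        pull(paste0("education", e))
    }
  }
  eff
}
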