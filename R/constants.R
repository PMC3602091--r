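# Canonical factor levels shared by the generator, preprocessing and models.
# Reference levels (first element) follow the published tables: age < 40,
# female, no high-school degree, occupation unknown, survey year 2010,
# limitation code 1 ("not at all difficult").

msk_age_levels <- c("18-39", "40-44", "45-49", "50-54", "55-59",
                    "60-64", "65-69", "70+")

msk_sex_levels <- c("female", "male")

msk_education_levels <- c("no_hs", "hs", "baccalaureate", "post_baccalaureate")

msk_occupation_levels <- c(
  "unknown", "management", "finance", "computer", "architect",
  "social_sciences", "social_services", "legal", "education", "arts",
  "health_practitioner", "healthcare_support", "protective_services",
  "food_preparation", "cleaning", "personal_care", "sales",
  "administrative_support", "farm", "construction", "maintenance",
  "production", "transport", "military")

msk_years <- 2004:2010

# Eight activity-limitation items, in the survey's order. Codes 1-5:
# 1 = not at all difficult ... 5 = can't do at all.
msk_items <- c("walk", "climb", "sit", "reach", "stand", "stoop",
               "lift", "push")

msk_item_labels <- c(
  walk  = "Walk a quarter of a mile",
  climb = "Walk up 10 steps without resting",
  sit   = "Sit for about 2 hours",
  reach = "Reach up over your head",
  stand = "Stand or be on your feet for about 2 hours",
  stoop = "Stoop, bend, or kneel",
  lift  = "Lift or carry something as heavy as 10 pounds",
  push  = "Push or pull large objects")

msk_causes <- c("back", "injury", "msk", "arthritis")

msk_cause_cols <- paste0("cause_", msk_causes)
msk_item_cols  <- paste0("lim_", msk_items)

# Items entering the Physical Function Index; the remaining three
# (sit, reach, stand) are carried as separate covariates.
msk_index_items <- c("push", "lift", "climb", "stoop", "walk")
msk_nonindex_items <- c("sit", "reach", "stand")

msk_outcomes <- c("employment", "ssi", "income", "missed_days")

msk_cohort_columns <- c("id", "age_group", "sex", "education", "occupation",
                        "year", msk_item_cols, msk_cause_cols,
                        "employed", "ssi", "income_band", "missed_days")

`%||%` <- function(x, y) if (is.null(x)) y else x
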