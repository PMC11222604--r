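# Hand-scored fixture records: each value was scored against the
# reference cutoff table cell by cell, independently of the engine,
# and the resulting totals frozen here.
fixture_records <- function() {
  tibble::tribble(
    ~id, ~sex, ~fiber, ~carotene, ~riboflavin, ~niacin, ~vitamin_b6,
    ~total_folate, ~vitamin_b12, ~vitamin_c, ~vitamin_e, ~calcium,
    ~magnesium, ~zinc, ~copper, ~selenium, ~total_fat, ~iron,
    ~physical_activity, ~alcohol_g_per_day, ~bmi_kg_m2, ~smoking3,
    # A: male, mixed tertiles incl. several at-cutoff boundary values
    "A", "male", 25, 100, 1.80, 40, 1.74, 400, 4.40, 43.23, 9.57, 1200,
    262.33, 10.01, 1.54, 102.60, 104.62, 19,
    "high", 30, 27, "former",
    # B: female, every component at its maximum-scoring level
    "B", "female", 20, 250, 3, 30, 2, 400, 5, 100, 8.5, 1000,
    300, 11, 1.3, 110, 50, 9,
    "high", 0, 22, "never",
    # C: male, every component at its minimum-scoring level
    "C", "male", 10, 50, 1, 20, 1, 300, 3, 40, 5, 700,
    200, 9, 1, 100, 120, 20,
    "low", 35, 31, "current",
    # D: as B but with three dietary values missing
    "D", "female", NA, NA, NA, 30, 2, 400, 5, 100, 8.5, 1000,
    300, 11, 1.3, 110, 50, 9,
    "high", 0, 22, "never",
    # E: female, boundary values on the upper side of each cutoff
    "E", "female", 11.30, 57.61, 2.02, 23.50, 1.89, 385.50, 2.56, 90.36,
    5.03, 921.50, 211.01, 10.54, 0.88, 105.74, 77.44, 9.79,
    "moderate", 14.99, 18.49, "never"
  )
}

# totals obtained by independent hand scoring of fixture_records()
fixture_expected_totals <- c(A = 18, B = 40, C = 0, D = 34, E = 22)
fixture_expected_complete <- c(A = 20L, B = 20L, C = 20L, D = 17L, E = 20L)

small_config <- function(n = 200, seed = 1, ...) {
  cohort_config(n_participants = n, seed = seed, ...)
}

# raw cohort where each block fails exactly one exclusion stage, in
# stage order; `counts` = c(age, obs_incomplete, missing_sua,
# missing_covariate, clean)
exclusion_fixture <- function(counts, seed = 99) {
  n <- sum(counts)
  ch <- generate_cohort(cohort_config(n_participants = n, seed = seed,
                                      age_range = c(20, 70), missing_rate = 0))
  idx <- split(seq_len(n), rep(seq_along(counts), counts))
  if (counts[1] > 0) ch$age[idx[[1]]] <- 10
  if (counts[2] > 0) {
    for (comp in dietary_components()[1:4]) ch[[comp]][idx[[2]]] <- NA_real_
  }
  if (counts[3] > 0) ch$sua_umol_l[idx[[3]]] <- NA_real_
  if (counts[4] > 0) ch$race[idx[[4]]] <- NA_character_
  ch
}

# analysis-ready scored cohort (data-driven cutoffs = generative truth)
scored_cohort <- function(n = 2000, seed = 5, ...) {
  ch <- generate_cohort(cohort_config(n_participants = n, seed = seed,
                                      missing_rate = 0, ...))
  assign_quartiles(score_cohort(ch, derive_cutoffs(ch)))
}
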