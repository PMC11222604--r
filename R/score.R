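#' Score a tertile-mode component for one sex
#'
#' Applies the directional tertile rule: antioxidants score 0 for
#' `value <= c1`, 1 for `c1 < value <= c2`, 2 for `value > c2`;
#' pro-oxidants the reverse (highest tertile earns 0). Ties at a
#' cutoff fall to the lower tertile.
#'
#' @param value Numeric vector of intakes; `NA` propagates to an `NA`
#'   score (missing is signalled, never silently scored 0).
#' @param spec A single row of an [builtin_table1()]-style scoring
#'   table (tertile mode).
#' @param sex `"male"` or `"female"` (length 1 or recycled to `value`).
#' @return Integer scores in `{0, 1, 2}` (or `NA`).
#' @export
#' @examples
#' tab <- builtin_table1()
#' fib <- tab[tab$component == "fiber", ]
#' score_tertile_component(c(10, 15, 25), fib, "male")  # 0 1 2
score_tertile_component <- function(value, spec, sex) {
  stopifnot(nrow(spec) == 1L, spec$mode == "tertile")
  sex <- check_sex(sex, n = length(value))
  c1 <- ifelse(sex == "male", spec$male_c1, spec$female_c1)
  c2 <- ifelse(sex == "male", spec$male_c2, spec$female_c2)
  tert <- ifelse(value <= c1, 0L, ifelse(value <= c2, 1L, 2L))
  if (spec$direction == "pro-oxidant") tert <- 2L - tert
  as.integer(tert)
}

#' Score alcohol consumption
#'
#' Three drinking categories with sex-specific heavy thresholds:
#' heavy drinkers (>= 30 g/d men, >= 15 g/d women) score 0,
#' non-heavy drinkers (anything above zero but below the threshold)
#' score 1, and non-drinkers (exactly 0 g/d) score 2. The threshold
#' itself counts as heavy.
#'
#' @param grams_per_day Non-negative numeric vector; `NA` gives `NA`.
#' @param sex `"male"`/`"female"`, length 1 or matching
#'   `grams_per_day`.
#' @param thresholds Named numeric: heavy-drinking cutoffs in g/d.
#' @return Integer scores in `{0, 1, 2}`.
#' @export
#' @examples
#' score_alcohol(c(0, 10, 35), "male")   # 2 1 0
#' score_alcohol(15, "female")           # 0 (boundary is heavy)
score_alcohol <- function(grams_per_day, sex,
                          thresholds = c(male = 30, female = 15)) {
  if (any(grams_per_day < 0, na.rm = TRUE)) {
    abort("alcohol intake must be non-negative (g/d)")
  }
  sex <- check_sex(sex, n = length(grams_per_day))
  thr <- unname(thresholds[sex])
  as.integer(ifelse(grams_per_day >= thr, 0L,
                    ifelse(grams_per_day > 0, 1L, 2L)))
}

#' Categorise BMI for OBS scoring
#'
#' @param bmi Positive numeric vector (kg/m2).
#' @return Character vector: `"underweight"` (< 18.5), `"normal"`
#'   (18.5-24.9), `"overweight"` (25.0-29.9), `"obese"` (>= 30).
#' @export
bmi_category <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) abort("bmi must be positive")
  cut_pts <- c(-Inf, 18.5, 25, 30, Inf)
  labs <- c("underweight", "normal", "overweight", "obese")
  as.character(cut(bmi, cut_pts, labels = labs, right = FALSE))
}

score_categorical <- function(component, value, sex, table) {
  uw <- attr(table, "underweight_score") %||% 2L
  check_levels <- function(x, map, what) {
    bad <- !is.na(x) & !x %in% names(map)
    if (any(bad)) {
      abort(sprintf("unknown %s category '%s'", what, x[which(bad)[1]]))
    }
    unname(map[x])
  }
  switch(component,
    physical_activity = check_levels(value, category_score_map("physical_activity"),
                                     "physical activity"),
    smoking = check_levels(value, category_score_map("smoking"), "smoking"),
    bmi = unname(category_score_map("bmi", uw)[bmi_category(value)]),
    alcohol = score_alcohol(value, sex,
                            thresholds = attr(table, "alcohol_thresholds")),
    abort(sprintf("unknown categorical component '%s'", component))
  )
}

#' Compute the Oxidative Balance Score for a cohort
#'
#' Scores every component of every participant against a scoring
#' table and sums the points. The total ranges 0-40 (20 components,
#' 0-2 points each). Because eligible participants may still lack up
#' to three components, two missing-data policies are offered:
#' `"zero"` (default) lets missing components contribute 0 points and
#' reports completeness via `n_complete`; `"prorate"` rescales the sum
#' of present scores to the full 20 components
#' (`sum * 20 / n_complete`, non-integer in general).
#'
#' `ln_obs`, the natural log of the total, is the exposure used by
#' the association models; it is defined only when the total is at
#' least 1 and is `NA` otherwise.
#'
#' @param records Cohort tibble: `sex` plus one column per component
#'   (dietary intakes, `physical_activity`, `alcohol` as
#'   `alcohol_g_per_day`, `bmi` as `bmi_kg_m2`, `smoking` as
#'   `smoking3`). An `id` column is carried through if present.
#' @param table An [builtin_table1()]-style scoring table.
#' @param missing_policy `"zero"` or `"prorate"`.
#' @return A tibble with `id`, one `score_<component>` column per
#'   component (integer 0-2 or `NA`), `n_complete` (0-20),
#'   `obs_total`, and `ln_obs`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 50, seed = 1))
#' compute_obs(cohort, builtin_table1())
compute_obs <- function(records, table = builtin_table1(),
                        missing_policy = c("zero", "prorate")) {
  missing_policy <- match.arg(missing_policy)
  table <- validate_scoring_table(table)
  stopifnot(is.data.frame(records))
  if (!"sex" %in% names(records) || anyNA(records$sex)) {
    abort("records must carry a complete 'sex' column")
  }
  sex <- check_sex(records$sex, n = nrow(records))

  # map component names to record columns
  col_of <- c(
    setNames(dietary_components(), dietary_components()),
    physical_activity = "physical_activity",
    alcohol = "alcohol_g_per_day",
    bmi = "bmi_kg_m2",
    smoking = "smoking3"
  )
  absent <- col_of[!col_of %in% names(records)]
  if (length(absent) > 0) {
    abort(sprintf("records lack columns for components: %s",
                  paste(names(absent), collapse = ", ")))
  }

  scores <- matrix(NA_integer_, nrow = nrow(records), ncol = 20L,
                   dimnames = list(NULL, table$component))
  for (i in seq_len(nrow(table))) {
    comp <- table$component[i]
    x <- records[[col_of[[comp]]]]
    scores[, comp] <- if (table$mode[i] == "tertile") {
      score_tertile_component(x, table[i, ], sex)
    } else {
      score_categorical(comp, x, sex, table)
    }
  }

  n_complete <- as.integer(rowSums(!is.na(scores)))
  raw_sum <- rowSums(scores, na.rm = TRUE)
  obs_total <- switch(missing_policy,
    zero = as.numeric(raw_sum),
    prorate = ifelse(n_complete > 0, raw_sum * 20 / n_complete, NA_real_)
  )
  out <- tibble(
    id = if ("id" %in% names(records)) records$id else as.character(seq_len(nrow(records)))
  )
  score_cols <- as_tibble(as.data.frame(scores))
  names(score_cols) <- paste0("score_", colnames(scores))
  out <- dplyr::bind_cols(out, score_cols)
  out$n_complete <- n_complete
  out$obs_total <- obs_total
  out$ln_obs <- ifelse(!is.na(obs_total) & obs_total >= 1, log(obs_total), NA_real_)
  out
}

#' Score a cohort and append OBS columns
#'
#' Convenience wrapper around [compute_obs()] that joins
#' `n_complete`, `obs_total` and `ln_obs` back onto the input records.
#'
#' @inheritParams compute_obs
#' @return `records` with `n_complete`, `obs_total`, `ln_obs` added.
#' @export
score_cohort <- function(records, table = builtin_table1(),
                         missing_policy = c("zero", "prorate")) {
  res <- compute_obs(records, table, missing_policy)
  records$n_complete <- res$n_complete
  records$obs_total <- res$obs_total
  records$ln_obs <- res$ln_obs
  records
}

check_sex <- function(sex, n) {
  sex <- as.character(sex)
  if (length(sex) == 1L) sex <- rep(sex, n)
  if (length(sex) != n) abort("sex must have length 1 or match the data")
  bad <- !sex %in% c("male", "female")
  if (any(bad)) {
    abort(sprintf("sex must be 'male' or 'female' (got '%s')", sex[which(bad)[1]]))
  }
  sex
}

`%||%` <- function(x, y) if (is.null(x)) y else x
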