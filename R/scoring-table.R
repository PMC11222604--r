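#' The 20 OBS components and their scoring metadata
#'
#' The Oxidative Balance Score sums 0-2 points over 20 components:
#' 14 dietary antioxidants and 2 dietary pro-oxidants (total fat, iron)
#' scored against sex-specific intake tertiles, plus 4 lifestyle
#' factors (physical activity, alcohol, BMI, smoking) scored
#' categorically. This registry fixes the component names used
#' throughout the package: dietary components double as cohort column
#' names.
#'
#' @return A tibble with one row per component: `component`, `class`
#'   (`"dietary"`/`"lifestyle"`), `direction`
#'   (`"antioxidant"`/`"pro-oxidant"`), `mode`
#'   (`"tertile"`/`"categorical"`), and `unit`.
#' @export
#' @examples
#' obs_components()
obs_components <- function() {
  tibble(
    component = c(
      "fiber", "carotene", "riboflavin", "niacin", "vitamin_b6",
      "total_folate", "vitamin_b12", "vitamin_c", "vitamin_e",
      "calcium", "magnesium", "zinc", "copper", "selenium",
      "total_fat", "iron",
      "physical_activity", "alcohol", "bmi", "smoking"
    ),
    class = rep(c("dietary", "lifestyle"), c(16L, 4L)),
    direction = c(
      rep("antioxidant", 14L), "pro-oxidant", "pro-oxidant",
      "antioxidant", "pro-oxidant", "pro-oxidant", "pro-oxidant"
    ),
    mode = rep(c("tertile", "categorical"), c(16L, 4L)),
    unit = c(
      "g/d", "RE/d", "mg/d", "mg/d", "mg/d", "mcg/d", "mcg/d", "mg/d",
      "mg ATE/d", "mg/d", "mg/d", "mg/d", "mg/d", "mcg/d", "g/d", "mg/d",
      "category", "g/d", "kg/m2", "category"
    )
  )
}

#' Names of the 16 dietary (tertile-scored) OBS components
#' @return Character vector of length 16.
#' @export
dietary_components <- function() {
  reg <- obs_components()
  reg$component[reg$mode == "tertile"]
}

#' Fixed OBS scoring table with published sex-specific cutoffs
#'
#' Returns the reference scoring table: for each tertile-scored
#' component, the male and female cutoff pair `(c1, c2)` delimiting
#' the three intake tertiles, and for the lifestyle components the
#' fixed category-to-score maps. Scoring is directional: antioxidants
#' earn 0/1/2 points for the low/middle/high tertile, pro-oxidants the
#' reverse. Alcohol uses sex-specific heavy-drinking thresholds
#' (30 g/d men, 15 g/d women) rather than tertiles.
#'
#' Ties at a cutoff fall into the lower tertile group, i.e. the
#' tertile intervals are `<= c1`, `(c1, c2]`, `> c2`.
#'
#' @param underweight_score Score (0, 1 or 2) assigned to underweight
#'   BMI (< 18.5 kg/m2), a category absent from the published
#'   obesity/overweight/normal scheme. Default 2 (treated as
#'   non-adipose, like normal weight).
#' @return A `obs_scoring_table`: a tibble with columns `component`,
#'   `class`, `direction`, `mode`, `male_c1`, `male_c2`, `female_c1`,
#'   `female_c2` (cutoffs are `NA` for categorical components), with
#'   attributes `alcohol_thresholds` (named numeric, heavy-drinking
#'   g/d per sex) and `underweight_score`.
#' @seealso [derive_cutoffs()] for data-driven tertile cutoffs,
#'   [compute_obs()] to apply the table.
#' @export
#' @examples
#' tab <- builtin_table1()
#' tab[tab$component == "selenium", c("male_c1", "male_c2")]
builtin_table1 <- function(underweight_score = 2L) {
  stopifnot(underweight_score %in% 0:2)
  cuts <- matrix(
    c(
      # male c1, male c2, female c1, female c2
      13.20,   20.80,   11.30,  17.30,   # fiber
      53.58,  176.81,   57.60, 198.53,   # carotene
       1.80,    2.64,    1.40,   2.02,   # riboflavin
      22.93,   32.73,   16.29,  23.49,   # niacin
       1.74,    2.59,    1.29,   1.89,   # vitamin B6
     328.33,  495.00,  257.39, 385.50,   # total folate
       3.66,    4.40,    2.56,   4.50,   # vitamin B12
      43.23,  104.13,   41.45,  90.35,   # vitamin C
       6.02,    9.57,    5.03,   7.98,   # vitamin E
     751.00, 1130.50,  610.67, 921.50,   # calcium
     262.33,  366.50,  211.00, 293.00,   # magnesium
      10.00,   14.65,    7.24,  10.54,   # zinc
       1.08,    1.53,    0.88,   1.25,   # copper
     102.60,  145.48,   74.77, 105.73,   # selenium
      70.92,  104.62,   53.03,  77.44,   # total fat
      12.72,   18.74,    9.79,  14.12    # iron
    ),
    ncol = 4L, byrow = TRUE
  )
  tab <- obs_components()
  tab$male_c1 <- tab$male_c2 <- tab$female_c1 <- tab$female_c2 <- NA_real_
  tab[tab$mode == "tertile", c("male_c1", "male_c2", "female_c1", "female_c2")] <-
    as.data.frame(cuts)
  new_scoring_table(tab, underweight_score = as.integer(underweight_score))
}

new_scoring_table <- function(tab, underweight_score = 2L,
                              alcohol_thresholds = c(male = 30, female = 15)) {
  attr(tab, "alcohol_thresholds") <- alcohol_thresholds
  attr(tab, "underweight_score") <- underweight_score
  class(tab) <- c("obs_scoring_table", class(tab))
  validate_scoring_table(tab)
}

validate_scoring_table <- function(tab) {
  reg <- obs_components()
  if (nrow(tab) != 20L || !setequal(tab$component, reg$component)) {
    abort("a scoring table must contain exactly the 20 registered OBS components")
  }
  if (anyDuplicated(tab$component)) abort("duplicate component names in scoring table")
  n_anti <- sum(tab$direction == "antioxidant")
  if (n_anti != 15L) {
    abort(sprintf("expected 15 antioxidant and 5 pro-oxidant components, got %d antioxidants", n_anti))
  }
  ter <- tab[tab$mode == "tertile", ]
  bad_m <- !is.na(ter$male_c1) & !(ter$male_c1 < ter$male_c2)
  bad_f <- !is.na(ter$female_c1) & !(ter$female_c1 < ter$female_c2)
  if (any(bad_m) || any(bad_f)) {
    offenders <- unique(ter$component[bad_m | bad_f])
    abort(sprintf(
      "tertile cutoffs must satisfy c1 < c2; violated for: %s",
      paste(offenders, collapse = ", ")
    ))
  }
  if (any(is.na(ter$male_c1) | is.na(ter$male_c2) |
          is.na(ter$female_c1) | is.na(ter$female_c2))) {
    abort("tertile components require complete cutoffs for both sexes")
  }
  tab
}

#' Category-to-score maps for the lifestyle OBS components
#'
#' Physical activity is the lone lifestyle antioxidant (low/moderate/
#' high activity earn 0/1/2); smoking, adiposity and alcohol are
#' pro-oxidants (never smoker, normal weight and non-drinker earn the
#' full 2 points). The alcohol map applies to drinking categories
#' derived from grams/day via the sex-specific heavy thresholds (see
#' [score_alcohol()]).
#'
#' @param component One of `"physical_activity"`, `"smoking"`,
#'   `"bmi"`, `"alcohol"`.
#' @param underweight_score Score for the underweight BMI category
#'   (see [builtin_table1()]).
#' @return Named integer vector mapping category to score.
#' @export
category_score_map <- function(component = c("physical_activity", "smoking",
                                             "bmi", "alcohol"),
                               underweight_score = 2L) {
  component <- match.arg(component)
  switch(component,
    physical_activity = c(low = 0L, moderate = 1L, high = 2L),
    smoking = c(current = 0L, former = 1L, never = 2L),
    bmi = c(obese = 0L, overweight = 1L, normal = 2L,
            underweight = as.integer(underweight_score)),
    alcohol = c(heavy = 0L, nonheavy = 1L, none = 2L)
  )
}

#' Derive sex-stratified tertile cutoffs from a cohort
#'
#' Recomputes the `(c1, c2)` cutoff pair of every tertile-scored
#' component as the empirical 1/3 and 2/3 quantiles of the non-missing
#' values within each sex, mirroring how the published cutoffs were
#' obtained. Quantiles use the inverse-empirical-CDF definition
#' (`type = 1`), so for values 1..9 the cutoffs are (3, 6).
#'
#' @param records A cohort tibble with a `sex` column
#'   (`"male"`/`"female"`) and one column per dietary component (see
#'   [dietary_components()]).
#' @param components Components to re-derive; defaults to all 16
#'   tertile components. Must be a subset of them.
#' @param table Scoring table whose cutoffs are replaced; categorical
#'   components are passed through untouched.
#' @return An `obs_scoring_table` with updated cutoffs.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 500, seed = 1))
#' derive_cutoffs(cohort)
derive_cutoffs <- function(records, components = dietary_components(),
                           table = builtin_table1()) {
  stopifnot(is.data.frame(records), "sex" %in% names(records))
  bad <- setdiff(components, dietary_components())
  if (length(bad) > 0) {
    abort(sprintf("not tertile-scored components: %s", paste(bad, collapse = ", ")))
  }
  missing_cols <- setdiff(components, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("records lack component columns: %s", paste(missing_cols, collapse = ", ")))
  }
  for (comp in components) {
    for (sx in c("male", "female")) {
      x <- records[[comp]][records$sex == sx]
      x <- x[!is.na(x)]
      if (length(x) < 3L) {
        abort(sprintf(
          "cannot derive tertiles for component '%s', sex '%s': only %d non-missing values (need >= 3)",
          comp, sx, length(x)
        ))
      }
      cc <- unname(quantile(x, probs = c(1, 2) / 3, type = 1))
      if (cc[1] >= cc[2]) {
        abort(sprintf(
          "degenerate tertile cutoffs for component '%s', sex '%s': c1 = c2 = %g",
          comp, sx, cc[1]
        ))
      }
      i <- table$component == comp
      if (sx == "male") {
        table$male_c1[i] <- cc[1]; table$male_c2[i] <- cc[2]
      } else {
        table$female_c1[i] <- cc[1]; table$female_c2[i] <- cc[2]
      }
    }
  }
  validate_scoring_table(table)
}
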