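#' Convert serum uric acid from mg/dL to umol/L
#'
#' Uses 59.48 umol/L per mg/dL and rounds to the nearest integer, the
#' convention under which the diagnostic thresholds 7 and 6 mg/dL map
#' to 416 and 357 umol/L.
#'
#' @param mg_dl Numeric vector in mg/dL.
#' @return Numeric vector in umol/L (integer-valued).
#' @export
#' @examples
#' mgdl_to_umol(c(7, 6))  # 416 357
mgdl_to_umol <- function(mg_dl) round(mg_dl * 59.48)

#' Hyperuricemia case definition
#'
#' @param male_threshold,female_threshold SUA thresholds in umol/L
#'   (default 416 and 357, i.e. 7 and 6 mg/dL); the comparison is
#'   `>=` and the male threshold must exceed the female one.
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(male_threshold = mgdl_to_umol(7),
                         female_threshold = mgdl_to_umol(6)) {
  if (male_threshold <= 0 || female_threshold <= 0) {
    abort("hyperuricemia thresholds must be positive")
  }
  if (male_threshold <= female_threshold) {
    abort("male threshold must exceed the female threshold")
  }
  structure(list(male_threshold = male_threshold,
                 female_threshold = female_threshold,
                 comparison = ">="),
            class = "outcome_spec")
}

#' Classify hyperuricemia from serum uric acid
#'
#' Hyperuricemia is SUA >= 416 umol/L (7 mg/dL) in men and
#' >= 357 umol/L (6 mg/dL) in women. Depends only on `(sua, sex)`.
#'
#' @param sua_umol_l Numeric SUA in umol/L; must be non-missing
#'   (records with missing SUA are excluded upstream).
#' @param sex `"male"`/`"female"`, length 1 or matching `sua_umol_l`.
#' @param spec An [outcome_spec()].
#' @return Logical vector.
#' @export
#' @examples
#' classify_hyperuricemia(c(416, 415.9), "male")   # TRUE FALSE
#' classify_hyperuricemia(400, c("female", "male")[1])
classify_hyperuricemia <- function(sua_umol_l, sex, spec = outcome_spec()) {
  if (anyNA(sua_umol_l)) {
    abort("missing SUA: records without serum uric acid must be excluded before classification")
  }
  sex <- check_sex(sex, n = length(sua_umol_l))
  thr <- ifelse(sex == "male", spec$male_threshold, spec$female_threshold)
  sua_umol_l >= thr
}

#' Covariates required for the fully adjusted model
#' @return Character vector of cohort column names.
#' @export
default_required_covariates <- function() {
  c("age", "race", "education", "pir", "bmi_kg_m2",
    "smoking_binary", "drinking_binary",
    "hypertension", "diabetes", "hyperlipidemia")
}

#' Apply the complete-case exclusion chain
#'
#' Filters a raw cohort in the fixed published order: (1) age below
#' `min_age`; (2) OBS completeness, removing participants with fewer
#' than `min_complete` of the 20 components non-missing (i.e. the
#' "<= 16 complete" rule when `min_complete = 17`); (3) missing serum
#' uric acid; (4) missing any required covariate. Each record is
#' removed at the first failing stage only, so the stage counts sum
#' exactly to `initial_n - final_n`.
#'
#' @param records Cohort tibble with `age`, the 20 component columns,
#'   `sua_umol_l`, and the covariates.
#' @param min_age Minimum age retained (years).
#' @param min_complete Minimum number of non-missing OBS components.
#' @param required_covariates Columns that must be non-missing.
#' @return A list: `records` (retained rows) and `report`, an
#'   exclusion-report tibble with columns `stage` and `n` covering
#'   `initial_n`, the four removal stages, and `final_n`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 300, seed = 3,
#'                                         age_range = c(12, 80)))
#' apply_exclusions(cohort)$report
apply_exclusions <- function(records, min_age = 18, min_complete = 17,
                             required_covariates = default_required_covariates()) {
  stopifnot(is.data.frame(records))
  comp_cols <- c(dietary_components(), "physical_activity", "alcohol_g_per_day",
                 "bmi_kg_m2", "smoking3")
  need <- unique(c("age", comp_cols, "sua_umol_l", required_covariates))
  absent <- setdiff(need, names(records))
  if (length(absent) > 0) {
    abort(sprintf("records lack columns: %s", paste(absent, collapse = ", ")))
  }

  initial_n <- nrow(records)
  n_complete <- rowSums(!is.na(records[comp_cols]))

  fail_age <- is.na(records$age) | records$age < min_age
  fail_obs <- !fail_age & n_complete < min_complete
  fail_sua <- !fail_age & !fail_obs & is.na(records$sua_umol_l)
  fail_cov <- !fail_age & !fail_obs & !fail_sua &
    !complete.cases(records[required_covariates])

  keep <- !(fail_age | fail_obs | fail_sua | fail_cov)
  report <- tibble(
    stage = c("initial_n", "removed_age_lt_min", "removed_obs_incomplete",
              "removed_missing_sua", "removed_missing_covariates", "final_n"),
    n = c(initial_n, sum(fail_age), sum(fail_obs), sum(fail_sua),
          sum(fail_cov), sum(keep))
  )
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Empirical quartile scheme for a (possibly discrete) exposure
#'
#' Builds quartile boundaries from the data by a rank-based rule that
#' handles heavy ties in an integer-valued score: the k-th boundary
#' is the largest observed value whose cumulative count does not
#' exceed `k * n / 4`. Ties at a boundary therefore fall into the
#' lower quartile, producing contiguous integer ranges on an integer
#' score. Because the rule uses only the ordering of the values, the
#' resulting labels are invariant under any strictly increasing
#' transform (e.g. OBS vs lnOBS).
#'
#' @param x Numeric vector (no `NA`) with at least 4 distinct values.
#' @return A `quartile_scheme`: list with `boundaries` (length 3,
#'   strictly increasing; quartile k is
#'   `(boundaries[k-1], boundaries[k]]`) and `labels`.
#' @export
#' @examples
#' quartile_scheme(rep(3:37, times = 35:1))
quartile_scheme <- function(x) {
  if (anyNA(x)) abort("quartile scheme requires non-missing values")
  n <- length(x)
  ux <- sort(unique(x))
  if (length(ux) < 4L) {
    abort(sprintf("need at least 4 distinct values to form quartiles (got %d)",
                  length(ux)))
  }
  cum <- cumsum(tabulate(match(x, ux), nbins = length(ux)))
  bnd <- vapply(1:3, function(k) {
    ok <- which(cum <= k * n / 4)
    if (length(ok) == 0) {
      abort(sprintf("cannot form a non-empty quartile %d: smallest value already exceeds k*n/4", k))
    }
    ux[max(ok)]
  }, numeric(1))
  if (any(diff(bnd) <= 0)) {
    abort("tied data collapse adjacent quartile boundaries; quartiles are not defined")
  }
  structure(list(boundaries = bnd, labels = paste0("Q", 1:4)),
            class = "quartile_scheme")
}

cut_quartiles <- function(x, scheme) {
  b <- scheme$boundaries
  idx <- 1L + (x > b[1]) + (x > b[2]) + (x > b[3])
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Assign exposure quartiles to a scored cohort
#'
#' Labels each participant Q1-Q4 by the empirical quartiles of the
#' chosen exposure over the cohort itself (or a supplied scheme).
#' Labels computed on `obs_total` and on `ln_obs` are identical
#' element-wise, since the log is strictly increasing on the retained
#' scores.
#'
#' @param records Scored cohort (see [score_cohort()]); the exposure
#'   column must be non-missing.
#' @param variable `"obs_total"` or `"ln_obs"`.
#' @param scheme Optional [quartile_scheme()]; derived from the data
#'   when `NULL`.
#' @return `records` with a `quartile` factor column added; the
#'   scheme is attached as attribute `"quartile_scheme"`.
#' @export
assign_quartiles <- function(records, variable = c("obs_total", "ln_obs"),
                             scheme = NULL) {
  variable <- match.arg(variable)
  x <- records[[variable]]
  if (is.null(x)) abort(sprintf("records lack column '%s'", variable))
  if (anyNA(x)) {
    abort(sprintf("'%s' has missing values; exclude or rescore before quartiling", variable))
  }
  if (is.null(scheme)) scheme <- quartile_scheme(x)
  records$quartile <- cut_quartiles(x, scheme)
  attr(records, "quartile_scheme") <- scheme
  records
}
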