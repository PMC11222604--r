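#' Configuration for the synthetic NHANES-like cohort generator
#'
#' Bundles and validates every knob of [generate_cohort()]. Defaults
#' describe a US-adult-like population: right-skewed (log-normal)
#' sex-specific nutrient intakes whose 1/3 and 2/3 quantiles sit at
#' the reference scoring cutoffs of [builtin_table1()], categorical
#' lifestyle factors and covariate prevalences near published NHANES
#' 2011-2018 marginals, sex-specific serum uric acid with a
#' configurable negative lnOBS effect, and independent componentwise
#' missingness in the dietary intakes.
#'
#' @param n_participants Number of records to draw (>= 1).
#' @param seed Integer seed; identical configurations produce
#'   bit-identical cohorts.
#' @param prop_male Fraction male, in `[0, 1]`.
#' @param age_range Length-2 numeric, min/max age in years (uniform).
#' @param nutrient_params Named list (one entry per dietary
#'   component) of per-sex log-normal parameters:
#'   `list(male = c(meanlog=, sdlog=), female = ...)`. The default
#'   solves meanlog/sdlog so the distribution tertile boundaries equal
#'   the [builtin_table1()] cutoffs.
#' @param lifestyle_probs Named list with category probabilities for
#'   `physical_activity` (low/moderate/high), `smoking3`
#'   (never/former/current), `bmi` (underweight/normal/overweight/
#'   obese, sampled as a category then drawn uniformly inside its
#'   kg/m2 range), and `alcohol` (`p_zero` point mass at 0 plus
#'   `meanlog`/`sdlog` of the positive log-normal part, g/d).
#' @param sua_baseline Per-sex list `c(mean=, sd=)`: the SUA
#'   intercept (umol/L) and Gaussian noise SD entering
#'   `SUA = mean + obs_effect * lnOBS + N(0, sd)`.
#' @param obs_effect True change in expected SUA (umol/L) per unit
#'   lnOBS; negative mimics an antioxidant-protective association.
#'   lnOBS here is computed with data-driven (cohort-derived) tertile
#'   cutoffs, so the generative slope is exactly the estimand the
#'   association models target.
#' @param covariate_prevalences Named fractions for `hypertension`,
#'   `diabetes`, `hyperlipidemia`.
#' @param race_probs,education_probs Named category probabilities for
#'   the two categorical covariates.
#' @param pir_params `c(mean=, sd=)` for the poverty-to-income ratio
#'   (normal, truncated at 0).
#' @param intake_cor Latent diet-quality correlation in `[0, 1)`:
#'   every dietary log-intake loads on a shared per-person factor
#'   with this correlation, leaving each component's log-normal
#'   marginal untouched while correlating components as real intakes
#'   are (people who eat more tend to eat more of everything). The
#'   default 0.55 puts the simulated OBS standard deviation near the
#'   ~7.2 observed in US-adult cohorts; 0 gives independent intakes
#'   and a much narrower score (about 3.6 SD), because the reversed
#'   pro-oxidant scores then cancel none of the antioxidant spread.
#' @param missing_rate Per-component probability that a dietary value
#'   is missing, in `[0, 1]`.
#' @return A validated `cohort_config` list.
#' @export
#' @examples
#' cohort_config(n_participants = 100, seed = 42)
cohort_config <- function(n_participants,
                          seed,
                          prop_male = 0.497,
                          age_range = c(18, 80),
                          nutrient_params = default_nutrient_params(),
                          lifestyle_probs = default_lifestyle_probs(),
                          sua_baseline = list(male = c(mean = 400, sd = 60),
                                              female = c(mean = 325, sd = 60)),
                          obs_effect = -14,
                          covariate_prevalences = c(hypertension = 0.36,
                                                    diabetes = 0.14,
                                                    hyperlipidemia = 0.35),
                          race_probs = c("Mexican American" = 0.132,
                                         "Other Hispanic" = 0.100,
                                         "Non-Hispanic White" = 0.412,
                                         "Non-Hispanic Black" = 0.214,
                                         "Other Race" = 0.142),
                          education_probs = c("Less than 9th grade" = 0.076,
                                              "9-11th grade" = 0.118,
                                              "High school graduate" = 0.227,
                                              "College degree" = 0.321,
                                              "College graduate or above" = 0.258),
                          pir_params = c(mean = 2.53, sd = 1.62),
                          intake_cor = 0.55,
                          missing_rate = 0.02) {
  cfg <- list(
    n_participants = n_participants, seed = seed, prop_male = prop_male,
    age_range = age_range, nutrient_params = nutrient_params,
    lifestyle_probs = lifestyle_probs, sua_baseline = sua_baseline,
    obs_effect = obs_effect, covariate_prevalences = covariate_prevalences,
    race_probs = race_probs, education_probs = education_probs,
    pir_params = pir_params, intake_cor = intake_cor,
    missing_rate = missing_rate
  )
  validate_cohort_config(cfg)
}

config_error <- function(field, msg) {
  abort(sprintf("invalid cohort configuration: field '%s' %s", field, msg))
}

check_probs <- function(p, field) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    config_error(field, "must contain probabilities in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    config_error(field, sprintf("probabilities must sum to 1 (got %.12f)", sum(p)))
  }
  invisible(p)
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(n_participants) || length(n_participants) != 1 ||
        n_participants < 1 || n_participants != floor(n_participants)) {
      config_error("n_participants", "must be a positive integer")
    }
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      config_error("seed", "must be a finite integer")
    }
    if (!is.numeric(prop_male) || prop_male < 0 || prop_male > 1) {
      config_error("prop_male", "must be a fraction in [0, 1]")
    }
    if (length(age_range) != 2 || age_range[1] > age_range[2] || age_range[1] < 0) {
      config_error("age_range", "must be an increasing non-negative (min, max) pair")
    }
    miss <- setdiff(dietary_components(), names(nutrient_params))
    if (length(miss) > 0) {
      config_error("nutrient_params",
                   sprintf("lacks components: %s", paste(miss, collapse = ", ")))
    }
    for (comp in dietary_components()) {
      for (sx in c("male", "female")) {
        p <- nutrient_params[[comp]][[sx]]
        if (is.null(p) || !all(c("meanlog", "sdlog") %in% names(p)) ||
            p[["sdlog"]] <= 0) {
          config_error("nutrient_params",
                       sprintf("['%s']$%s needs meanlog and sdlog > 0", comp, sx))
        }
      }
    }
    check_probs(lifestyle_probs$physical_activity, "lifestyle_probs$physical_activity")
    check_probs(lifestyle_probs$smoking3, "lifestyle_probs$smoking3")
    check_probs(lifestyle_probs$bmi, "lifestyle_probs$bmi")
    al <- lifestyle_probs$alcohol
    if (is.null(al) || al[["p_zero"]] < 0 || al[["p_zero"]] > 1 || al[["sdlog"]] <= 0) {
      config_error("lifestyle_probs$alcohol", "needs p_zero in [0,1] and sdlog > 0")
    }
    for (sx in c("male", "female")) {
      b <- sua_baseline[[sx]]
      if (is.null(b) || b[["sd"]] <= 0) {
        config_error("sua_baseline", sprintf("$%s needs a positive sd", sx))
      }
    }
    if (!is.numeric(obs_effect) || length(obs_effect) != 1) {
      config_error("obs_effect", "must be a single number")
    }
    for (nm in c("hypertension", "diabetes", "hyperlipidemia")) {
      p <- covariate_prevalences[[nm]]
      if (is.null(p) || p < 0 || p > 1) {
        config_error("covariate_prevalences", sprintf("$%s must be in [0, 1]", nm))
      }
    }
    check_probs(race_probs, "race_probs")
    check_probs(education_probs, "education_probs")
    if (pir_params[["sd"]] <= 0) config_error("pir_params", "needs sd > 0")
    if (!is.numeric(intake_cor) || intake_cor < 0 || intake_cor >= 1) {
      config_error("intake_cor", "must be in [0, 1)")
    }
    if (missing_rate < 0 || missing_rate > 1) {
      config_error("missing_rate", "must be in [0, 1]")
    }
  })
  structure(cfg, class = "cohort_config")
}

#' Default log-normal intake parameters matched to the reference cutoffs
#'
#' For each dietary component and sex, solves the log-normal
#' `meanlog`/`sdlog` so that the distribution's 1/3 and 2/3 quantiles
#' equal the [builtin_table1()] cutoffs `(c1, c2)`:
#' `meanlog = (log c1 + log c2) / 2`,
#' `sdlog = (log c2 - log c1) / (2 * qnorm(2/3))`. Tertile occupancy
#' under data-driven cutoffs is then automatically balanced and
#' derived cutoffs concentrate near the reference ones.
#'
#' @return Named list, one entry per dietary component, each
#'   `list(male = c(meanlog, sdlog), female = ...)`.
#' @export
default_nutrient_params <- function() {
  tab <- builtin_table1()
  tab <- tab[tab$mode == "tertile", ]
  z <- qnorm(2 / 3)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    mk <- function(c1, c2) {
      c(meanlog = (log(c1) + log(c2)) / 2, sdlog = (log(c2) - log(c1)) / (2 * z))
    }
    list(male = mk(tab$male_c1[i], tab$male_c2[i]),
         female = mk(tab$female_c1[i], tab$female_c2[i]))
  })
  setNames(out, tab$component)
}

#' Default lifestyle category probabilities
#'
#' BMI category and drinking/smoking margins sit near published
#' NHANES 2011-2018 adult marginals; physical activity has no
#' published marginal and uses a roughly even split.
#'
#' @return Named list consumed by [cohort_config()].
#' @export
default_lifestyle_probs <- function() {
  list(
    physical_activity = c(low = 0.35, moderate = 0.35, high = 0.30),
    smoking3 = c(never = 0.558, former = 0.220, current = 0.222),
    bmi = c(underweight = 0.015, normal = 0.266, overweight = 0.323, obese = 0.396),
    alcohol = c(p_zero = 0.34, meanlog = log(8), sdlog = 1.1)
  )
}

# kg/m2 ranges the BMI categories are drawn uniformly within
bmi_ranges <- list(
  underweight = c(16, 18.5), normal = c(18.5, 25),
  overweight = c(25, 30), obese = c(30, 45)
)

#' Generate a synthetic NHANES-like cohort
#'
#' Draws `n_participants` records per the configuration, then wires
#' in the ground-truth exposure-outcome structure: the cohort is
#' scored with its own sex-stratified data-driven tertile cutoffs
#' ([derive_cutoffs()]), and serum uric acid is generated as
#' `sua_baseline[sex]$mean + obs_effect * lnOBS + N(0, sua_baseline[sex]$sd)`,
#' so the true conditional slope of SUA on lnOBS equals
#' `obs_effect`. Dietary missingness is applied afterwards (missing
#' completely at random, independently per component), leaving the
#' generative SUA untouched.
#'
#' In the rare case `obs_total = 0` (lnOBS undefined), the effect
#' term is dropped for that record and `ln_obs` is `NA`.
#'
#' @param config A [cohort_config()].
#' @return A tibble, one row per participant, with identifiers,
#'   demographics, the 16 dietary intakes, lifestyle factors
#'   (`physical_activity`, `alcohol_g_per_day`, `smoking3`,
#'   `bmi_kg_m2`), covariates (`race`, `education`, `pir`,
#'   `smoking_binary`, `drinking_binary`, `hypertension`, `diabetes`,
#'   `hyperlipidemia`), `sua_umol_l`, `weight` (frequency weight,
#'   all 1), and the generative truth columns `obs_total_true`,
#'   `ln_obs_true`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 200, seed = 7))
#' dplyr::count(cohort, sex)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- validate_cohort_config(config)
  n <- as.integer(config$n_participants)
  withr::with_seed(as.integer(config$seed), {
    sex <- sample(c("male", "female"), n, replace = TRUE,
                  prob = c(config$prop_male, 1 - config$prop_male))
    age <- round(runif(n, config$age_range[1], config$age_range[2]), 1)

    rec <- tibble(id = sprintf("P%06d", seq_len(n)), sex = sex, age = age)

    # shared diet-quality factor: log-intakes are equicorrelated at
    # intake_cor while each component keeps its exact log-normal marginal
    rho <- config$intake_cor
    u <- rnorm(n)
    for (comp in dietary_components()) {
      pm <- config$nutrient_params[[comp]]
      zi <- sqrt(rho) * u + sqrt(1 - rho) * rnorm(n)
      x <- numeric(n)
      for (sx in c("male", "female")) {
        i <- sex == sx
        x[i] <- exp(pm[[sx]][["meanlog"]] + pm[[sx]][["sdlog"]] * zi[i])
      }
      rec[[comp]] <- x
    }

    lp <- config$lifestyle_probs
    rec$physical_activity <- sample(names(lp$physical_activity), n, TRUE,
                                    prob = lp$physical_activity)
    rec$smoking3 <- sample(names(lp$smoking3), n, TRUE, prob = lp$smoking3)
    bmi_cat <- sample(names(lp$bmi), n, TRUE, prob = lp$bmi)
    rec$bmi_kg_m2 <- vapply(bmi_cat, function(k) {
      r <- bmi_ranges[[k]]
      runif(1, r[1], r[2])
    }, numeric(1), USE.NAMES = FALSE)
    drinks <- runif(n) >= lp$alcohol[["p_zero"]]
    rec$alcohol_g_per_day <- ifelse(
      drinks, rlnorm(n, lp$alcohol[["meanlog"]], lp$alcohol[["sdlog"]]), 0
    )

    rec$race <- sample(names(config$race_probs), n, TRUE, prob = config$race_probs)
    rec$education <- sample(names(config$education_probs), n, TRUE,
                            prob = config$education_probs)
    rec$pir <- pmax(0, rnorm(n, config$pir_params[["mean"]], config$pir_params[["sd"]]))
    rec$smoking_binary <- ifelse(rec$smoking3 == "never", "no", "yes")
    rec$drinking_binary <- ifelse(rec$alcohol_g_per_day > 0, "yes", "no")
    for (nm in c("hypertension", "diabetes", "hyperlipidemia")) {
      p <- config$covariate_prevalences[[nm]]
      rec[[nm]] <- ifelse(runif(n) < p, "yes", "no")
    }

    # ground-truth exposure and outcome (data-driven cutoffs, pre-missingness)
    tab <- derive_cutoffs(rec)
    obs <- compute_obs(rec, tab)
    rec$obs_total_true <- obs$obs_total
    rec$ln_obs_true <- obs$ln_obs
    mu <- ifelse(sex == "male",
                 config$sua_baseline$male[["mean"]],
                 config$sua_baseline$female[["mean"]])
    sdn <- ifelse(sex == "male",
                  config$sua_baseline$male[["sd"]],
                  config$sua_baseline$female[["sd"]])
    effect <- ifelse(is.na(obs$ln_obs), 0, config$obs_effect * obs$ln_obs)
    rec$sua_umol_l <- mu + effect + rnorm(n, 0, sdn)

    if (config$missing_rate > 0) {
      for (comp in dietary_components()) {
        drop <- runif(n) < config$missing_rate
        rec[[comp]][drop] <- NA_real_
      }
    }

    rec$weight <- 1
    rec
  })
}

#' Write / read a cohort as UTF-8 comma-separated text
#'
#' Missing values are written as empty fields (never a sentinel), so
#' `read_cohort(write_cohort(x, p))` is the identity on the data.
#' `read_cohort` is a tolerant reader: unknown extra columns are kept;
#' malformed numeric cells raise a parse error naming row and column.
#'
#' @param records Cohort tibble.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(records, path) {
  stopifnot(is.data.frame(records))
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such cohort file: %s", path))
  numeric_cols <- c("age", dietary_components(), "alcohol_g_per_day",
                    "bmi_kg_m2", "pir", "sua_umol_l", "weight",
                    "obs_total_true", "ln_obs_true",
                    "n_complete", "obs_total", "ln_obs")
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               name_repair = "minimal"))
  if (length(hdr) == 0 || anyDuplicated(hdr) || any(hdr == "")) {
    abort(sprintf("malformed cohort header in %s", path))
  }
  spec <- lapply(hdr, function(h) {
    if (h %in% numeric_cols) readr::col_double() else readr::col_character()
  })
  out <- suppressWarnings(
    readr::read_csv(path, col_types = do.call(readr::cols, setNames(spec, hdr)),
                    na = "", progress = FALSE)
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    # row indices count the header as file row 1
    abort(sprintf("parse error in %s at file row %d, column %d: expected %s, got '%s'",
                  path, probs$row[1], probs$col[1], probs$expected[1], probs$actual[1]))
  }
  out
}
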