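#' Specify a Model 1/2/3 association analysis
#'
#' Fixes the outcome, the exposure parameterisation, and the nested
#' covariate sets: Model 1 is unadjusted; Model 2 adjusts for age,
#' sex, and race/ethnicity; Model 3 additionally adjusts for BMI
#' category, education, smoking, drinking, diabetes, hypertension,
#' and hyperlipidemia. Reference levels are female sex, Non-Hispanic
#' White race, lowest education, "no" for the binary covariates, and
#' Q1 for the exposure quartile.
#'
#' @param model 1, 2 or 3.
#' @param outcome `"sua"` (linear regression of SUA in umol/L) or
#'   `"hyperuricemia"` (logistic regression).
#' @param exposure `"lnobs_continuous"` (the `ln_obs` column) or
#'   `"lnobs_quartile"` (the `quartile` factor).
#' @param weights Optional name of a frequency-weight column; the
#'   default fits are unweighted (design-based survey variance is
#'   out of scope).
#' @return A `model_spec` list with the resolved covariate set.
#' @export
#' @examples
#' model_spec(3, "hyperuricemia", "lnobs_quartile")
model_spec <- function(model = 1,
                       outcome = c("sua", "hyperuricemia"),
                       exposure = c("lnobs_continuous", "lnobs_quartile"),
                       weights = NULL) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  if (!model %in% 1:3) abort("model must be 1, 2 or 3")
  covariates <- switch(model,
    character(0),
    c("age", "sex", "race"),
    c("age", "sex", "race", "bmi_cat", "education",
      "smoking_binary", "drinking_binary",
      "diabetes", "hypertension", "hyperlipidemia")
  )
  structure(list(model = model, outcome = outcome, exposure = exposure,
                 covariates = covariates, weights = weights),
            class = "model_spec")
}

# reference levels for the categorical covariates
reference_levels <- list(
  sex = "female",
  race = "Non-Hispanic White",
  education = "Less than 9th grade",
  bmi_cat = "normal",
  smoking_binary = "no", drinking_binary = "no",
  hypertension = "no", diabetes = "no", hyperlipidemia = "no"
)

# build the model frame: outcome, exposure term, releveled covariates
build_model_data <- function(records, spec) {
  d <- as_tibble(records)
  if (spec$outcome == "sua") {
    if (!"sua_umol_l" %in% names(d)) abort("records lack 'sua_umol_l'")
    d$.outcome <- d$sua_umol_l
  } else {
    if (!"hyperuricemia" %in% names(d)) {
      d$hyperuricemia <- classify_hyperuricemia(d$sua_umol_l, d$sex)
    }
    d$.outcome <- as.integer(d$hyperuricemia)
  }
  if (spec$exposure == "lnobs_continuous") {
    if (!"ln_obs" %in% names(d)) abort("records lack 'ln_obs'; score the cohort first")
    d$.exposure <- d$ln_obs
  } else {
    if (!"quartile" %in% names(d)) abort("records lack 'quartile'; run assign_quartiles() first")
    d$.exposure <- factor(d$quartile, levels = paste0("Q", 1:4))
  }
  if ("bmi_cat" %in% spec$covariates && !"bmi_cat" %in% names(d)) {
    d$bmi_cat <- bmi_category(d$bmi_kg_m2)
  }
  for (v in spec$covariates) {
    if (!v %in% names(d)) abort(sprintf("records lack covariate '%s'", v))
    ref <- reference_levels[[v]]
    if (!is.null(ref)) d[[v]] <- relevel_safe(d[[v]], ref)
  }
  d$.w <- if (is.null(spec$weights)) 1 else d[[spec$weights]]
  if (anyNA(d$.w) || any(d$.w <= 0)) abort("weights must be positive and non-missing")
  used <- c(".outcome", ".exposure", spec$covariates)
  if (anyNA(d[used])) {
    abort("missing values among modelled variables; apply_exclusions() must run first")
  }
  d
}

relevel_safe <- function(x, ref) {
  x <- if (is.factor(x)) x else factor(x)
  if (ref %in% levels(x)) stats::relevel(x, ref) else x
}

model_formula <- function(spec) {
  rhs <- c(".exposure", spec$covariates)
  as.formula(paste(".outcome ~", paste(rhs, collapse = " + ")))
}

check_aliased <- function(fit) {
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(sprintf("singular design: aliased terms %s",
                  paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  cf
}

# Wald extraction of the exposure terms; logistic results are
# exponentiated to ORs. Reference quartile is emitted as a flagged row.
extract_terms <- function(fit, spec, n_used) {
  cf <- check_aliased(fit)
  V <- vcov(fit)
  keep <- grep("^\\.exposure", names(cf), value = TRUE)
  est <- cf[keep]
  se <- sqrt(diag(V)[keep])
  z <- qnorm(0.975)
  p <- 2 * pnorm(-abs(est / se))
  term <- if (spec$exposure == "lnobs_continuous") "lnOBS" else sub("^\\.exposure", "", keep)
  out <- tibble(
    term = term,
    estimate = unname(est),
    ci_low = unname(est - z * se),
    ci_high = unname(est + z * se),
    p_value = unname(p),
    n_used = n_used,
    is_ref = FALSE
  )
  if (spec$outcome == "hyperuricemia") {
    out$estimate <- exp(out$estimate)
    out$ci_low <- exp(out$ci_low)
    out$ci_high <- exp(out$ci_high)
  }
  if (spec$exposure == "lnobs_quartile") {
    ref <- tibble(term = "Q1",
                  estimate = if (spec$outcome == "hyperuricemia") 1 else 0,
                  ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                  n_used = n_used, is_ref = TRUE)
    out <- dplyr::bind_rows(ref, out)
  }
  out$measure <- if (spec$outcome == "hyperuricemia") "or" else "beta"
  out
}

#' Linear association of lnOBS with serum uric acid
#'
#' Ordinary (optionally frequency-weighted) least squares of SUA
#' (umol/L) on the exposure plus the model's covariates, with
#' large-sample Wald 95% confidence intervals. The quartile exposure
#' reports Q2-Q4 contrasts against the Q1 reference.
#'
#' @param records Analysis-ready cohort (scored, excluded,
#'   quartiled).
#' @param spec A [model_spec()] with `outcome = "sua"`.
#' @return Tibble with one row per exposure term: `term`, `estimate`
#'   (beta, umol/L), `ci_low`, `ci_high`, `p_value`, `n_used`,
#'   `is_ref`, `measure`.
#' @export
fit_linear <- function(records, spec = model_spec(1, "sua")) {
  stopifnot(inherits(spec, "model_spec"), spec$outcome == "sua")
  d <- build_model_data(records, spec)
  if (is.factor(d$.exposure) && dplyr::n_distinct(d$.exposure) < 2 ||
      !is.factor(d$.exposure) && sd(d$.exposure) == 0) {
    abort("singular design: exposure is constant")
  }
  fit <- lm(model_formula(spec), data = d, weights = .w)
  extract_terms(fit, spec, n_used = nrow(d))
}

#' Logistic association of lnOBS with hyperuricemia
#'
#' Maximum-likelihood logistic regression; exposure coefficients are
#' exponentiated to odds ratios with Wald 95% intervals.
#'
#' @param records Analysis-ready cohort.
#' @param spec A [model_spec()] with `outcome = "hyperuricemia"`.
#' @return Tibble as in [fit_linear()], with `estimate` an OR.
#' @export
fit_logistic <- function(records, spec = model_spec(1, "hyperuricemia")) {
  stopifnot(inherits(spec, "model_spec"), spec$outcome == "hyperuricemia")
  d <- build_model_data(records, spec)
  if (dplyr::n_distinct(d$.outcome) < 2) {
    abort("outcome has a single class; logistic fit undefined")
  }
  fit <- suppressWarnings(
    glm(model_formula(spec), data = d, family = binomial(), weights = .w)
  )
  if (!fit$converged) abort("logistic fit did not converge (possible separation)")
  mu <- fitted(fit)
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    abort("fitted probabilities numerically 0 or 1: data are (quasi-)separated")
  }
  extract_terms(fit, spec, n_used = nrow(d))
}

#' Crude quartile odds ratios from a 4 x 2 count table
#'
#' Closed-form cross-product odds ratios of each quartile against Q1
#' with Woolf (log-OR normal-approximation) 95% intervals,
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. Numerically identical to an
#' unadjusted categorical logistic regression on the same counts.
#'
#' @param cases Named vector of case counts per quartile (first
#'   element is the reference).
#' @param noncases Named vector of non-case counts, same order.
#' @return Tibble with one row per quartile (`is_ref` marks Q1):
#'   `term`, `estimate` (OR), `ci_low`, `ci_high`, `p_value`,
#'   `n_used`, `measure`.
#' @export
#' @examples
#' crude_quartile_or(cases = c(Q1 = 872, Q2 = 771, Q3 = 746, Q4 = 522),
#'                   noncases = c(Q1 = 2654, Q2 = 2977, Q3 = 3280, Q4 = 3274))
crude_quartile_or <- function(cases, noncases) {
  if (length(cases) != length(noncases) || length(cases) < 2) {
    abort("cases and noncases must be equal-length vectors (>= 2 strata)")
  }
  if (any(c(cases, noncases) <= 0)) {
    abort("all cell counts must be positive; apply continuity handling explicitly before calling")
  }
  if (is.null(names(cases))) names(cases) <- paste0("Q", seq_along(cases))
  z <- qnorm(0.975)
  a1 <- cases[1]; b1 <- noncases[1]
  rows <- lapply(seq_along(cases), function(k) {
    if (k == 1) {
      return(tibble(term = names(cases)[1], estimate = 1, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_,
                    n_used = sum(cases) + sum(noncases), is_ref = TRUE))
    }
    or <- (cases[k] * b1) / (noncases[k] * a1)
    se <- sqrt(1 / cases[k] + 1 / noncases[k] + 1 / a1 + 1 / b1)
    tibble(term = names(cases)[k],
           estimate = unname(or),
           ci_low = unname(exp(log(or) - z * se)),
           ci_high = unname(exp(log(or) + z * se)),
           p_value = unname(2 * pnorm(-abs(log(or) / se))),
           n_used = sum(cases) + sum(noncases),
           is_ref = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out$measure <- "or"
  out
}

#' Stratified association with an interaction test
#'
#' Refits the model within each level of a stratifier (the stratifier
#' itself dropped from the covariate set) and tests effect
#' modification via the exposure-by-stratifier product term in the
#' pooled model: a Wald chi-square on the product coefficients by
#' default, or a likelihood-ratio test with `test = "lrt"`.
#'
#' Strata smaller than `min_n`, or without both outcome classes for
#' the logistic outcome, are skipped with a warning and listed in the
#' result.
#'
#' @param records Analysis-ready cohort.
#' @param spec A [model_spec()].
#' @param stratifier Name of a categorical (or logical) cohort
#'   column with at least two observed levels.
#' @param min_n Minimum stratum size fitted.
#' @param test `"wald"` or `"lrt"` for the interaction p-value.
#' @return A `subgroup_result` list: `strata` (per-stratum exposure
#'   estimates as in [fit_linear()], with a `stratum` column),
#'   `p_interaction`, `stratifier`, and `skipped`.
#' @export
subgroup_analysis <- function(records, spec, stratifier, min_n = 100,
                              test = c("wald", "lrt")) {
  test <- match.arg(test)
  stopifnot(inherits(spec, "model_spec"))
  if (!stratifier %in% names(records)) {
    abort(sprintf("records lack stratifier column '%s'", stratifier))
  }
  s <- as.character(records[[stratifier]])
  levels_obs <- unique(s[!is.na(s)])
  if (length(levels_obs) < 2) {
    abort(sprintf("stratifier '%s' has a single observed level", stratifier))
  }
  sub_spec <- spec
  sub_spec$covariates <- setdiff(spec$covariates, stratifier)

  fit_fun <- if (spec$outcome == "sua") fit_linear else fit_logistic
  strata <- list(); skipped <- character(0)
  for (lev in sort(levels_obs)) {
    rows <- records[!is.na(s) & s == lev, , drop = FALSE]
    ok <- nrow(rows) >= min_n &&
      (spec$outcome == "sua" ||
         dplyr::n_distinct(classify_hyperuricemia(rows$sua_umol_l, rows$sex)) == 2)
    if (!ok) {
      warn(sprintf("stratum '%s' of '%s' skipped (n = %d)", lev, stratifier, nrow(rows)))
      skipped <- c(skipped, lev)
      next
    }
    res <- fit_fun(rows, sub_spec)
    res$stratum <- lev
    strata[[lev]] <- res
  }

  # pooled model with the product term, over the fitted strata only
  fitted_levels <- setdiff(sort(levels_obs), skipped)
  if (length(fitted_levels) < 2) {
    abort(sprintf("fewer than two fitted strata for '%s'; no interaction test", stratifier))
  }
  pool <- records[!is.na(s) & s %in% fitted_levels, , drop = FALSE]
  d <- build_model_data(pool, sub_spec)
  d$.stratum <- relevel_safe(as.character(pool[[stratifier]]), fitted_levels[1])
  rhs <- c(".exposure * .stratum", sub_spec$covariates)
  f_full <- as.formula(paste(".outcome ~", paste(rhs, collapse = " + ")))
  f_null <- as.formula(paste(".outcome ~",
                             paste(c(".exposure", ".stratum", sub_spec$covariates),
                                   collapse = " + ")))
  if (spec$outcome == "sua") {
    full <- lm(f_full, data = d, weights = .w)
    null <- lm(f_null, data = d, weights = .w)
  } else {
    full <- suppressWarnings(glm(f_full, data = d, family = binomial(), weights = .w))
    null <- suppressWarnings(glm(f_null, data = d, family = binomial(), weights = .w))
  }
  p_int <- if (test == "wald") {
    cf <- check_aliased(full)
    V <- vcov(full)
    ix <- grep("^\\.exposure.*:\\.stratum", names(cf))
    if (length(ix) == 0) abort("no interaction coefficients found in pooled model")
    b <- cf[ix]
    W <- drop(t(b) %*% solve(V[ix, ix, drop = FALSE]) %*% b)
    pchisq(W, df = length(ix), lower.tail = FALSE)
  } else {
    if (spec$outcome == "sua") {
      anova(null, full)[2, "Pr(>F)"]
    } else {
      anova(null, full, test = "LRT")[2, "Pr(>Chi)"]
    }
  }
  structure(list(strata = dplyr::bind_rows(strata),
                 p_interaction = unname(p_int),
                 stratifier = stratifier,
                 skipped = skipped),
            class = "subgroup_result")
}
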