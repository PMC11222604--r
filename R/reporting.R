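fmt2 <- function(x) sprintf("%.2f", x)

#' Format a percentage cell as "count (pp.pp%)"
#' @param count,total Non-negative counts, `total > 0`.
#' @return Character, e.g. `"319 (10.96%)"`.
#' @export
#' @examples
#' format_count_pct(319, 2911)
format_count_pct <- function(count, total) {
  stopifnot(all(total > 0))
  sprintf("%d (%s%%)", as.integer(count), fmt2(100 * count / total))
}

#' Format a p-value for publication tables
#'
#' Four decimal places, with values below 1e-4 printed `"<0.0001"`.
#' @param p Numeric vector in `[0, 1]` (or `NA`).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
}

#' Baseline characteristics table stratified by outcome or quartile
#'
#' Publication-style "Table 1": categorical variables as
#' `count (percent%)` per stratum with a chi-square independence
#' test, continuous variables as `mean +/- dispersion` with a
#' two-sample t-test (two strata) or one-way ANOVA (more).
#' Percentages are computed within stratum and printed at 2 dp, so
#' each categorical variable's levels sum to 100% up to rounding.
#'
#' @param records Cohort tibble; the stratifier column must be
#'   non-missing for every record.
#' @param stratifier Column name to stratify on (e.g. a
#'   hyperuricemia indicator or the OBS `quartile`).
#' @param continuous,categorical Character vectors of variable
#'   names; defaults cover the standard covariate set when present.
#' @param dispersion `"sd"` (default; matches the +/- spreads
#'   printed at these sample sizes) or `"se"`.
#' @return A `baseline_table` tibble: `variable`, `level`, one
#'   formatted column per stratum, and `p_value` on each variable's
#'   first row. Stratum sizes are in attribute `"stratum_n"`.
#' @export
baseline_table <- function(records, stratifier,
                           continuous = intersect(c("age", "sua_umol_l", "pir", "obs_total"),
                                                  names(records)),
                           categorical = intersect(c("sex", "race", "bmi_cat", "education",
                                                     "hypertension", "hyperlipidemia",
                                                     "diabetes", "smoking_binary",
                                                     "drinking_binary"),
                                                   names(records)),
                           dispersion = c("sd", "se")) {
  dispersion <- match.arg(dispersion)
  stopifnot(is.data.frame(records))
  if (!stratifier %in% names(records)) {
    abort(sprintf("records lack stratifier column '%s'", stratifier))
  }
  if ("bmi_cat" %in% categorical && !"bmi_cat" %in% names(records) &&
      "bmi_kg_m2" %in% names(records)) {
    records$bmi_cat <- bmi_category(records$bmi_kg_m2)
  }
  g <- records[[stratifier]]
  if (anyNA(g)) abort("stratifier must be non-missing for every record")
  g <- if (is.factor(g)) droplevels(g) else factor(g)
  strata <- levels(g)
  if (any(table(g) == 0)) abort("empty stratum in baseline table")
  n_strata <- as.integer(table(g))

  rows <- list()
  for (v in continuous) {
    x <- records[[v]]
    cells <- vapply(strata, function(s) {
      xs <- x[g == s]
      disp <- if (dispersion == "sd") sd(xs) else sd(xs) / sqrt(length(xs))
      sprintf("%s ± %s", fmt2(mean(xs)), fmt2(disp))
    }, character(1))
    p <- if (length(strata) == 2) {
      t.test(x ~ g)$p.value
    } else {
      summary(aov(x ~ g))[[1]][["Pr(>F)"]][1]
    }
    rows[[length(rows) + 1]] <- c(list(variable = v, level = ""),
                                  as.list(cells), list(p_value = p))
  }
  for (v in categorical) {
    x <- records[[v]]
    lv <- if (is.factor(x)) levels(droplevels(x)) else sort(unique(as.character(x)))
    tab <- table(factor(as.character(x), levels = lv), g)
    p <- if (length(lv) >= 2) {
      suppressWarnings(chisq.test(tab)$p.value)
    } else {
      NA_real_
    }
    for (j in seq_along(lv)) {
      cells <- vapply(seq_along(strata), function(k) {
        format_count_pct(tab[j, k], n_strata[k])
      }, character(1))
      names(cells) <- strata
      rows[[length(rows) + 1]] <- c(list(variable = v, level = lv[j]),
                                    as.list(cells),
                                    list(p_value = if (j == 1) p else NA_real_))
    }
  }
  out <- dplyr::bind_rows(lapply(rows, as_tibble))
  attr(out, "stratum_n") <- setNames(n_strata, strata)
  class(out) <- c("baseline_table", class(out))
  out
}

#' Format association results as publication rows
#'
#' Renders each term as `"estimate (ci_low, ci_high) p"` with 2-dp
#' estimates and intervals; reference rows print `"1.0(ref)"` (odds
#' ratios) or `"0"` (betas). Formatting is locale-independent.
#'
#' @param results Tibble from [fit_linear()], [fit_logistic()] or
#'   [crude_quartile_or()].
#' @return Tibble with `term`, `formatted`, `p` columns.
#' @export
#' @examples
#' association_table(crude_quartile_or(c(Q1 = 872, Q4 = 522),
#'                                     c(Q1 = 2654, Q4 = 3274)))
association_table <- function(results) {
  if (nrow(results) == 0) abort("no association results to format")
  is_ref <- if ("is_ref" %in% names(results)) results$is_ref else rep(FALSE, nrow(results))
  measure <- if ("measure" %in% names(results)) results$measure else rep("beta", nrow(results))
  formatted <- ifelse(
    is_ref,
    ifelse(measure == "or", "1.0(ref)", "0"),
    sprintf("%s (%s, %s)", fmt2(results$estimate),
            fmt2(results$ci_low), fmt2(results$ci_high))
  )
  tibble(term = results$term, formatted = formatted,
         p = format_p(results$p_value))
}

#' Serialise subgroup results for forest plotting
#'
#' One row per fitted stratum with the exposure estimate, its 95%
#' interval, the within-stratum p-value and sample size, and the
#' shared interaction p-value; skipped strata are flagged in the
#' `skipped` attribute. Column order is fixed so the file is a
#' stable, lossless round-trip via [readr::write_csv()].
#'
#' @param subgroup_results A `subgroup_result` from
#'   [subgroup_analysis()], or a list of them.
#' @return Tibble with columns `stratifier`, `stratum`, `term`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `n_used`,
#'   `p_interaction`.
#' @export
forest_data <- function(subgroup_results) {
  if (inherits(subgroup_results, "subgroup_result")) {
    subgroup_results <- list(subgroup_results)
  }
  rows <- lapply(subgroup_results, function(sg) {
    st <- sg$strata[!sg$strata$is_ref, , drop = FALSE]
    tibble(
      stratifier = sg$stratifier,
      stratum = st$stratum,
      term = st$term,
      estimate = st$estimate,
      ci_low = st$ci_low,
      ci_high = st$ci_high,
      p_value = st$p_value,
      n_used = st$n_used,
      p_interaction = sg$p_interaction
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- unlist(lapply(subgroup_results, function(sg) sg$skipped))
  out
}
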