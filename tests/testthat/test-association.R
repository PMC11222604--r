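test_that("crude quartile odds ratios match the closed-form cross product", {
  res <- crude_quartile_or(c(Q1 = 1, Q2 = 1), c(Q1 = 1, Q2 = 1))
  expect_equal(res$estimate[2], 1)
  res2 <- crude_quartile_or(cases = c(Q1 = 872, Q2 = 771, Q3 = 746, Q4 = 522),
                            noncases = c(Q1 = 2654, Q2 = 2977, Q3 = 3280, Q4 = 3274))
  expect_equal(round(res2$estimate[2:4], 2), c(0.79, 0.69, 0.49))
  expect_true(all(res2$ci_low[2:4] <= res2$estimate[2:4]))
  expect_true(all(res2$estimate[2:4] <= res2$ci_high[2:4]))
  expect_error(crude_quartile_or(c(Q1 = 0, Q2 = 5), c(Q1 = 3, Q2 = 4)),
               "continuity")
})

test_that("unadjusted categorical logistic ORs equal contingency ORs", {
  withr::with_seed(123, {
    for (rep in 1:10) {
      cases <- sample(20:200, 4)
      noncases <- sample(50:400, 4)
      oracle <- crude_quartile_or(setNames(cases, paste0("Q", 1:4)),
                                  setNames(noncases, paste0("Q", 1:4)))
      rec <- tibble::tibble(
        quartile = factor(rep(rep(paste0("Q", 1:4), 2), c(cases, noncases)),
                          levels = paste0("Q", 1:4)),
        hyperuricemia = rep(c(TRUE, FALSE), c(sum(cases), sum(noncases)))
      )
      fit <- fit_logistic(rec, model_spec(1, "hyperuricemia", "lnobs_quartile"))
      expect_equal(fit$estimate[2:4], oracle$estimate[2:4], tolerance = 1e-6)
    }
  })
})

test_that("linear model recovers the generative lnOBS slope", {
  hits <- vapply(1:100, function(s) {
    d <- scored_cohort(n = 5000, seed = 5000 + s, obs_effect = -14)
    r <- fit_linear(d, model_spec(1, "sua"))
    r$ci_low <= -14 && -14 <= r$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("zero-effect simulations give small slopes with ~95% CI coverage of 0", {
  res <- vapply(1:60, function(s) {
    d <- scored_cohort(n = 2000, seed = 6000 + s, obs_effect = 0)
    r <- fit_linear(d, model_spec(1, "sua"))
    c(beta = r$estimate, covers = r$ci_low <= 0 && 0 <= r$ci_high)
  }, c(beta = 0, covers = 0))
  expect_lt(abs(mean(res["beta", ])), 2)
  expect_gte(mean(res["covers", ]), 0.85)
})

test_that("a constant exposure raises a singularity error", {
  d <- scored_cohort(n = 200, seed = 77)
  d$ln_obs <- 3
  expect_error(fit_linear(d, model_spec(1, "sua")), "constant")
})

test_that("null-outcome simulations give ORs near 1", {
  d <- scored_cohort(n = 6000, seed = 88, obs_effect = 0)
  fit <- fit_logistic(d, model_spec(1, "hyperuricemia", "lnobs_quartile"))
  expect_true(all(abs(log(fit$estimate[2:4])) < 0.35))
})

test_that("nested models keep the same complete-case n", {
  d <- scored_cohort(n = 1500, seed = 14)
  ns <- vapply(1:3, function(m) {
    fit_linear(d, model_spec(m, "sua"))$n_used[1]
  }, integer(1))
  expect_true(all(ns == nrow(d)))
})

test_that("a strong protective effect yields monotone quartile ORs and Q4 recovery", {
  # obs_effect -30 with SUA noise 60 implies a markedly lower case
  # odds in Q4 than Q1; check sign, monotone trend and CI sanity
  d <- scored_cohort(n = 8000, seed = 33, obs_effect = -30)
  fit <- fit_logistic(d, model_spec(1, "hyperuricemia", "lnobs_quartile"))
  expect_lt(fit$estimate[4], 1)
  expect_true(all(diff(fit$estimate[2:4]) < 0.15))  # monotone up to noise
  expect_lt(fit$ci_high[4], 1)
})

test_that("subgroup analysis detects sex-specific slopes and stays calibrated under the null", {
  p_alt <- vapply(1:30, function(s) {
    d <- generate_cohort(cohort_config(n_participants = 6000, seed = 7000 + s,
                                       obs_effect = 0, missing_rate = 0))
    slope <- ifelse(d$sex == "male", -20, -8)
    d$sua_umol_l <- d$sua_umol_l + slope * d$ln_obs_true
    d <- assign_quartiles(score_cohort(d, derive_cutoffs(d)))
    subgroup_analysis(d, model_spec(1, "sua"), "sex")$p_interaction
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.80)

  p_null <- vapply(1:60, function(s) {
    d <- scored_cohort(n = 1200, seed = 8000 + s, obs_effect = -14)
    subgroup_analysis(d, model_spec(1, "sua"), "sex")$p_interaction
  }, numeric(1))
  # uniform under equal slopes: unremarkable rejection rate, spread mass
  expect_lte(mean(p_null < 0.05), 0.15)
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
})

test_that("per-stratum estimates drop the stratifier and cover both sexes", {
  d <- scored_cohort(n = 3000, seed = 15)
  sg <- subgroup_analysis(d, model_spec(2, "sua"), "sex")
  expect_setequal(sg$strata$stratum, c("male", "female"))
  expect_true(sg$p_interaction >= 0 && sg$p_interaction <= 1)
  expect_error(
    subgroup_analysis(dplyr::mutate(d, onelevel = "x"),
                      model_spec(1, "sua"), "onelevel"),
    "single observed level"
  )
})

test_that("small strata are skipped with a warning and recorded", {
  d <- scored_cohort(n = 500, seed = 16)
  d$grp <- c("tiny", rep(c("a", "b"), length.out = nrow(d) - 1))
  expect_warning(
    sg <- subgroup_analysis(d, model_spec(1, "sua"), "grp", min_n = 50),
    "skipped"
  )
  expect_true("tiny" %in% sg$skipped)
  expect_false("tiny" %in% sg$strata$stratum)
})
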