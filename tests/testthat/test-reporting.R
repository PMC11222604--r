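test_that("baseline cells are 'count (percent)' at two decimals", {
  expect_identical(format_count_pct(319, 2911), "319 (10.96%)")
  expect_identical(format_count_pct(1685, 2911), "1685 (57.88%)")
  expect_identical(format_count_pct(2911, 15096), "2911 (19.28%)")
})

test_that("baseline table reproduces published Table-2-style cells from counts", {
  # rebuild the two hyperuricemia strata with the published sex and
  # education margins, then let the table compute the percentages
  edu_lv <- c("Less than 9th grade", "9-11th grade", "High school graduate",
              "College degree", "College graduate or above")
  rec <- tibble::tibble(
    hyperuricemia = rep(c("no", "yes"), c(12185, 2911)),
    sex = c(rep(c("male", "female"), c(5818, 6367)),
            rep(c("male", "female"), c(1685, 1226))),
    education = c(rep(edu_lv, c(937, 1462, 2718, 3850, 3218)),
                  rep(edu_lv, c(209, 319, 715, 994, 674)))
  )
  bt <- baseline_table(rec, "hyperuricemia",
                       continuous = character(0),
                       categorical = c("sex", "education"))
  cell <- function(var, lev, col) bt[[col]][bt$variable == var & bt$level == lev]
  expect_identical(cell("education", "9-11th grade", "yes"), "319 (10.96%)")
  expect_identical(cell("education", "9-11th grade", "no"), "1462 (12.00%)")
  expect_identical(cell("sex", "male", "yes"), "1685 (57.88%)")
  expect_identical(cell("sex", "male", "no"), "5818 (47.75%)")
  expect_equal(attr(bt, "stratum_n"), c(no = 12185L, yes = 2911L))
})

test_that("categorical percentages sum to 100 within rounding, per stratum", {
  d <- scored_cohort(n = 800, seed = 41)
  d$hyperuricemia <- ifelse(classify_hyperuricemia(d$sua_umol_l, d$sex), "yes", "no")
  bt <- baseline_table(d, "hyperuricemia")
  pct <- function(cells) sum(as.numeric(sub(".*\\(([0-9.]+)%\\)", "\\1", cells)))
  for (v in unique(bt$variable[bt$level != ""])) {
    for (col in c("no", "yes")) {
      expect_lt(abs(pct(bt[[col]][bt$variable == v]) - 100), 0.05)
    }
  }
})

test_that("continuous rows show mean with SD (or SE on request) and a test p-value", {
  d <- withr::with_seed(1, tibble::tibble(g = rep(c("a", "b"), each = 50),
                                          age = c(rnorm(50, 40, 5), rnorm(50, 60, 5))))
  bt <- baseline_table(d, "g", continuous = "age", categorical = character(0))
  expect_match(bt$a[1], "^[0-9.]+ ± [0-9.]+$")
  expect_lt(bt$p_value[1], 1e-6)
  bt_se <- baseline_table(d, "g", continuous = "age",
                          categorical = character(0), dispersion = "se")
  spread <- function(x) as.numeric(sub(".* ± ", "", x))
  expect_lt(spread(bt_se$a[1]), spread(bt$a[1]))
})

test_that("single-level variables report one row at 100%", {
  d <- tibble::tibble(g = rep(c("x", "y"), each = 10), only = "all")
  bt <- baseline_table(d, "g", continuous = character(0), categorical = "only")
  expect_identical(bt$x, "10 (100.00%)")
  expect_true(is.na(bt$p_value))
})

test_that("association rows format as 'estimate (ci) p' with reference markers", {
  res <- tibble::tibble(term = c("Q1", "Q4"), estimate = c(1, 0.49),
                        ci_low = c(NA, 0.43), ci_high = c(NA, 0.55),
                        p_value = c(NA, 3e-9), is_ref = c(TRUE, FALSE),
                        measure = "or")
  ft <- association_table(res)
  expect_identical(ft$formatted, c("1.0(ref)", "0.49 (0.43, 0.55)"))
  expect_identical(ft$p, c("", "<0.0001"))
  res_b <- tibble::tibble(term = "Q1", estimate = 0, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          is_ref = TRUE, measure = "beta")
  expect_identical(association_table(res_b)$formatted, "0")
  expect_identical(format_p(0.0039), "0.0039")
})

test_that("forest data serialises strata with a shared interaction p and stable columns", {
  d <- scored_cohort(n = 1200, seed = 52)
  sg <- subgroup_analysis(d, model_spec(1, "sua"), "sex")
  fd <- forest_data(sg)
  expect_identical(names(fd),
                   c("stratifier", "stratum", "term", "estimate", "ci_low",
                     "ci_high", "p_value", "n_used", "p_interaction"))
  expect_equal(nrow(fd), 2)
  expect_equal(length(unique(fd$p_interaction)), 1)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(fd, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(fd), tolerance = 1e-12,
               ignore_attr = TRUE)
})
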