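test_that("error injection is exact, bounded, reproducible, and scoped to biohumoral columns", {
  tab <- generate_cohort(cohort_recipe(n_patients = 50, seed = 5))
  expect_identical(inject_error(tab, error_scenario("none")), tab)
  mx <- inject_error(tab, error_scenario("maximum"))
  expect_equal(mx$glucose, tab$glucose * 1.13, tolerance = 1e-12)
  expect_equal(mx$leptin, tab$leptin * 1.13, tolerance = 1e-12)
  expect_identical(mx$age, tab$age)
  expect_identical(mx$baseline_plaque_burden, tab$baseline_plaque_burden)
  expect_identical(mx$plaque_progression, tab$plaque_progression)
  down <- inject_error(tab, error_scenario("maximum", direction = "decrease"))
  expect_equal(down$glucose, tab$glucose * 0.87, tolerance = 1e-12)
  rnd <- inject_error(tab, error_scenario("random", seed = 42))
  ratios <- unlist(rnd[biohumoral_roster()]) / unlist(tab[biohumoral_roster()])
  expect_true(all(ratios >= 0.87 & ratios <= 1.13))
  expect_identical(inject_error(tab, error_scenario("random", seed = 42)), rnd)
  expect_false(identical(inject_error(tab, error_scenario("random", seed = 43)), rnd))
})

test_that("univariate screen recovers planted effects and not null variables", {
  tab <- generate_cohort(cohort_recipe(
    n_patients = 500, seed = 21,
    coefficients = c(age = 0.010, baseline_plaque_burden = -0.011, leptin = 0.05)))
  rep_bio <- univariate_screen(tab, vars = c(biohumoral_roster(),
                                             "age", "baseline_plaque_burden"))
  expect_true(rep_bio$significant[rep_bio$term == "leptin"])
  expect_true(rep_bio$significant[rep_bio$term == "baseline_plaque_burden"])
  expect_lt(rep_bio$estimate[rep_bio$term == "baseline_plaque_burden"], 0)
  null_vars <- setdiff(biohumoral_roster(), "leptin")
  expect_lt(mean(rep_bio$significant[rep_bio$term %in% null_vars]), 0.3)
  # CI always contains the estimate
  expect_true(all(rep_bio$ci_low <= rep_bio$estimate & rep_bio$estimate <= rep_bio$ci_high))
  # constant predictor skipped with warning
  tab$constant <- 1
  expect_warning(univariate_screen(tab, vars = c("glucose", "constant")), "constant")
})

test_that("uniform scaling of a predictor rescales its coefficient and leaves inference invariant", {
  tab <- generate_cohort(cohort_recipe(n_patients = 120, seed = 31,
                                       coefficients = c(glucose = 0.01)))
  base <- univariate_screen(tab, vars = "glucose")
  mx <- univariate_screen(inject_error(tab, error_scenario("maximum")), vars = "glucose")
  expect_equal(mx$estimate, base$estimate / 1.13, tolerance = 1e-9)
  expect_equal(mx$ci_low, base$ci_low / 1.13, tolerance = 1e-9)
  expect_equal(mx$p_value, base$p_value, tolerance = 1e-9)
})

test_that("multivariate fit recovers the planted model and rejects rank deficiency", {
  tab <- generate_cohort(cohort_recipe(n_patients = 500, seed = 41))
  fit <- multivariate_fit(tab, c("age", "baseline_plaque_burden", "glucose",
                                 "cholesterol", "SmartFFR"))
  expect_true(fit$significant[fit$term == "age"])
  expect_true(fit$significant[fit$term == "baseline_plaque_burden"])
  # null predictors: allow at most one chance rejection at alpha = 0.05
  expect_lte(sum(fit$significant[fit$term %in% c("glucose", "cholesterol", "SmartFFR")]), 1)
  tab$glucose_copy <- tab$glucose
  expect_error(multivariate_fit(tab, c("glucose", "glucose_copy")), "glucose_copy")
  # logistic option runs on a binary outcome
  tab_bin <- generate_cohort(cohort_recipe(n_patients = 300, outcome = "binary", seed = 8))
  fit_bin <- multivariate_fit(tab_bin, c("age", "baseline_plaque_burden"),
                              model = "logistic")
  expect_identical(nrow(fit_bin), 2L)
})

test_that("scenario comparison reports identical significant sets under uniform scaling", {
  tab <- generate_cohort(cohort_recipe(n_patients = 300, seed = 51,
                                       coefficients = c(age = 0.010,
                                                        baseline_plaque_burden = -0.011,
                                                        alkaline = 0.004)))
  vars <- c(biohumoral_roster(), "age", "baseline_plaque_burden")
  reports <- list(
    original = univariate_screen(tab, vars = vars),
    maximum = univariate_screen(inject_error(tab, error_scenario("maximum")), vars = vars),
    random = univariate_screen(inject_error(tab, error_scenario("random", seed = 3)),
                               vars = vars)
  )
  cmp <- compare_scenarios(reports)
  expect_equal(unname(cmp$jaccard[["maximum"]]), 1)   # exact equivariance
  expect_equal(unname(cmp$jaccard[["original"]]), 1)
  expect_identical(nrow(cmp$pattern), length(vars))
  expect_error(compare_scenarios(list(reports$original,
                                      univariate_screen(tab, vars = "glucose"))),
               "mismatched")
})
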