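test_that("ML logistic fit: intercept closed form, errors, dummy blocks", {
  rec <- records_from_2x2(300, 333, 0, 565)
  rec$occupation_expose <- 0L # no predictors used
  fit <- fit_logistic_ml(rec, character())
  expect_equal(fit$intercept, log(633 / 565), tolerance = 1e-8)
  expect_equal(nrow(fit$coefficients), 0)

  const <- rec
  const$arm <- 1L
  expect_error(fit_logistic_ml(const, character()),
               class = "famrisk_constant_outcome")

  cohort <- simulate_matched_cohort(cohort_config(n_pairs = 300, seed = 31))
  fit2 <- fit_logistic_ml(cohort, c("smoking", "relatives_with_cancer"))
  expect_equal(fit2$coefficients$term,
               c("smoking_light", "smoking_heavy", "relatives_1", "relatives_2plus"))
  expect_equal(fit2$coefficients$wald,
               (fit2$coefficients$estimate / fit2$coefficients$std_error)^2)
})

test_that("saturated single-factor fit reproduces the contingency OR to 10 digits", {
  fit <- fit_logistic_ml(records_from_2x2(201, 432, 127, 438),
                         "occupation_expose", tol = 1e-13)
  or_contingency <- 201 * 438 / (432 * 127)
  expect_lt(abs(fit$coefficients$or / or_contingency - 1), 1e-10)
})

test_that("separation and collinearity raise named errors", {
  rec <- records_from_2x2(50, 0, 0, 50)
  expect_error(fit_logistic_ml(rec, "occupation_expose"),
               class = "famrisk_separation")

  dup <- records_from_2x2(30, 20, 10, 40)
  dup$living_contact <- dup$occupation_expose # perfectly collinear
  expect_error(fit_logistic_ml(dup, c("occupation_expose", "living_contact")),
               class = "famrisk_rank_deficient")
})

test_that("wald_and_or arithmetic matches the reference derivations", {
  res <- wald_and_or(1.545, 0.211)
  expect_equal(round(res$or, 2), 4.69)
  expect_equal(round(res$ci_low, 2), 3.10)
  expect_equal(round(res$ci_high, 2), 7.09)
  expect_equal(res$wald, (1.545 / 0.211)^2)

  null <- wald_and_or(0, 1)
  expect_equal(null$wald, 0)
  expect_equal(null$p_value, 1)
  expect_equal(null$or, 1)
  expect_equal(null$ci_low, exp(-1.96))
  expect_equal(null$ci_high, exp(1.96))

  expect_error(wald_and_or(1, 0), class = "famrisk_bad_se")
})

test_that("score test at the null agrees with the likelihood-ratio scale", {
  cohort <- simulate_matched_cohort(independent_config(n_pairs = 2000, seed = 32))
  fit0 <- fit_logistic_ml(cohort, "sex")
  sc <- famrisk:::score_test_add(fit0, build_design(cohort, "smoking"))
  fit1 <- fit_logistic_ml(cohort, c("sex", "smoking"))
  lr <- 2 * (fit1$log_lik - fit0$log_lik)
  # large-sample agreement of the two chi-square statistics
  expect_lt(abs(sc$statistic - lr) / lr, 0.15)
  expect_equal(sc$df, 2)
})

test_that("empty candidate set yields the intercept-only model with empty trace", {
  cohort <- simulate_matched_cohort(cohort_config(n_pairs = 100, seed = 33))
  sel <- forward_stepwise(cohort, character())
  expect_equal(nrow(sel$trace), 0)
  expect_equal(length(sel$included), 0)
  expect_equal(sel$model$intercept, log(100 / 100), tolerance = 1e-6)
})

test_that("multi-level factors enter and leave as blocks", {
  cohort <- simulate_matched_cohort(independent_config(n_pairs = 1500, seed = 34))
  sel <- forward_stepwise(cohort, c("smoking", "sex"))
  sm <- sel$trace[sel$trace$term == "smoking", ]
  expect_true(nrow(sm) >= 1)
  expect_true(all(sm$df == 2))
  # never a lone dummy: final model holds both smoking dummies or neither
  has <- c("smoking_light", "smoking_heavy") %in% sel$model$coefficients$term
  expect_true(all(has) || all(!has))
  # a term never re-enters without an intervening removal
  for (tm in unique(sel$trace$term)) {
    acts <- sel$trace$action[sel$trace$term == tm]
    expect_true(all(rle(acts)$lengths[rle(acts)$values == "enter"] == 1))
  }
})

test_that("stepwise keeps a strong true effect and mostly rejects pure noise", {
  # one real effect (heavy smoking), age_group as the null candidate
  set.seed(3535)
  n_true <- 0L; n_noise <- 0L
  for (s in 1:40) {
    cfg <- independent_config(n_pairs = 600, seed = 100000 + s,
                              true_betas = c(smoking_heavy = 1.5),
                              alpha_pop = -7)
    cohort <- simulate_matched_cohort(cfg)
    sel <- forward_stepwise(cohort, c("smoking", "age_group"))
    if ("smoking" %in% sel$included) n_true <- n_true + 1L
    if ("age_group" %in% sel$included) n_noise <- n_noise + 1L
  }
  expect_gte(n_true, 39) # >= ~99% power
  expect_lte(n_noise, 6) # ~5% nominal inclusion, binomial upper bound
})

test_that("log-likelihood never decreases along the entry path", {
  cohort <- simulate_matched_cohort(independent_config(n_pairs = 1200, seed = 36))
  sel <- forward_stepwise(cohort, covariate_terms())
  entries <- sel$trace[sel$trace$action == "enter", ]
  expect_true(all(diff(entries$log_lik) > 0))
})
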