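test_that("intercept correction evaluates the sampling-offset formula exactly", {
  prior <- population_prior(633, 565, 49.7e-5)
  a <- correct_intercept(-0.867, prior)
  expect_equal(a, -0.867 - log(633 * (1 - 49.7e-5) / (565 * 49.7e-5)))
  expect_equal(round(a, 3), -8.587)

  # n1 = n0, q1 = q0 leaves the intercept untouched
  expect_equal(correct_intercept(1.5, population_prior(50, 50, 0.49999)), 1.5,
               tolerance = 1e-4)

  expect_equal(correct_intercept(0, population_prior(100, 100, 0.01)), -log(99))

  # round trip to machine precision
  offs <- log(633 * prior$q0 / (565 * prior$q1))
  expect_equal(a + offs, -0.867, tolerance = 1e-12)

  expect_error(population_prior(633, 565, 0), class = "famrisk_bad_prior")
  expect_error(population_prior(633, 565, 1), class = "famrisk_bad_prior")
  expect_error(population_prior(0, 565, 0.1), class = "famrisk_bad_prior")
})

test_that("corrected model wraps the base fit and its prior", {
  cm <- reference_corrected()
  expect_equal(cm$a, correct_intercept(-0.867, cm$prior))
  expect_error(correct_model(
    suppressWarnings(fit_conditional_logistic(discordant_pairs(8, 4), "occupation_expose")),
    reference_prior()), class = "famrisk_no_intercept")
})

test_that("stratum probabilities: expit vs odds approximation", {
  cm <- reference_corrected()
  p_ref <- zero_pattern()
  expect_equal(stratum_probability(p_ref, cm, mode = "odds_approx"), exp(cm$a))
  expect_equal(stratum_probability(p_ref, cm, mode = "expit"), plogis(cm$a))

  heavy <- zero_pattern(); heavy["smoking_heavy"] <- 1
  expect_equal(round(stratum_probability(heavy, cm), 6), 0.000874)

  # the two modes differ by exp(logit)^2 / (1 + exp(logit)) -- order p^2
  for (pat in list(p_ref, heavy)) {
    pe <- stratum_probability(pat, cm, mode = "expit")
    pa <- stratum_probability(pat, cm, mode = "odds_approx")
    expect_lt(abs(pa - pe), pa^2)
  }

  bad <- zero_pattern(); bad["smoking_light"] <- 1; bad["smoking_heavy"] <- 1
  expect_error(stratum_probability(bad, cm), class = "famrisk_bad_pattern")
  expect_error(stratum_probability(zero_pattern()[-1], cm),
               class = "famrisk_bad_pattern")

  # degradation warning when the approximation leaves its regime
  inflated <- correct_model(reference_model(), population_prior(633, 565, 0.05))
  big <- zero_pattern(); big[c("sex", "lung_disease_history", "smoking_heavy",
                               "occupation_expose", "relatives_2plus")] <- 1
  expect_warning(stratum_probability(big, inflated), class = "famrisk_approx_degrading")
})

test_that("relative risk is probability over incidence", {
  expect_equal(relative_risk(0.000497, 0.000497), 1)
  expect_equal(round(relative_risk(0.000186, 0.000497), 2), 0.37)
  expect_equal(round(relative_risk(0.031349, 0.000497), 2), 63.08)
  expect_error(relative_risk(0.1, 0), class = "famrisk_bad_prior")
})

test_that("risk bands follow the published strength-of-association scale", {
  expect_equal(as.character(risk_band(c(0.38, 1.05, 1.3, 1.76, 5, 63.08))),
               c("below-reference", "none", "weak", "moderate", "strong",
                 "very strong"))
  # gaps map to the nearest lower band
  expect_equal(as.character(risk_band(c(1.15, 9.5))), c("none", "strong"))
  expect_error(risk_band(0), class = "famrisk_bad_rr")
})

test_that("stratum enumeration: full grid size, ordering and observed mode", {
  cm <- reference_corrected()
  full <- enumerate_strata(model = cm, grid = "full")
  expect_equal(nrow(full), 72)
  expect_equal(full$row, 1:72)
  expect_true(all(diff(full$probability) >= 0))
  # rr strictly monotone in logit
  expect_true(all(diff(full$rr[order(full$logit)])[diff(sort(full$logit)) > 0] > 0))
  # mutually exclusive dummies never co-occur
  expect_true(all(full$smoking_light * full$smoking_heavy == 0))
  expect_true(all(full$relatives_1 * full$relatives_2plus == 0))

  # observed mode: one stratum per distinct pattern
  rec <- records_from_2x2(3, 4, 2, 1, term = "occupation_expose")
  rec$smoking[1:2] <- 2L # adds a third pattern
  obs <- enumerate_strata(rec, cm, grid = "observed")
  expect_equal(nrow(obs), 3)
  expect_error(enumerate_strata(model = cm, grid = "observed"),
               class = "famrisk_bad_config")
})

test_that("a large synthetic cohort approaches the full grid with monotone rr", {
  cfg <- independent_config(n_pairs = 4000, seed = 41)
  cohort <- simulate_matched_cohort(cfg)
  fit <- fit_logistic_ml(cohort, risk_model_terms())
  cm <- correct_model(fit, population_prior(cfg$n_pairs, cfg$n_pairs,
                                            implied_incidence(cfg)))
  obs <- enumerate_strata(cohort, cm, grid = "observed")
  expect_gt(nrow(obs), 55)
  expect_lte(nrow(obs), 72)
  expect_true(all(diff(obs$rr) >= 0))
})

test_that("corrected intercept recovers the generating population intercept", {
  cfg <- independent_config(n_pairs = 5000, seed = 42)
  cohort <- simulate_matched_cohort(cfg)
  fit <- fit_logistic_ml(cohort, covariate_terms())
  prior <- population_prior(cfg$n_pairs, cfg$n_pairs, implied_incidence(cfg))
  cm <- correct_model(fit, prior)
  expect_lt(abs(cm$a - cfg$alpha_pop), 3 * fit$intercept_se)
})
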