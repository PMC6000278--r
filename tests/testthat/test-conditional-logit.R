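test_that("matched-pair MLE with one binary term equals the discordant-pair ratio", {
  fit <- suppressWarnings(
    fit_conditional_logistic(discordant_pairs(30, 10, 20), "occupation_expose"))
  expect_equal(fit$coefficients$estimate, log(30 / 10), tolerance = 1e-7)
  expect_equal(fit$coefficients$or, 3, tolerance = 1e-6)
  expect_true(is.na(fit$intercept))
})

test_that("conditional log-likelihood at beta = 0 is -n_pairs log 2", {
  fit <- suppressWarnings(
    fit_conditional_logistic(discordant_pairs(10, 10, 0), "occupation_expose"))
  # symmetric discordance: MLE is 0, so the maximised value equals the null
  expect_equal(fit$coefficients$estimate, 0, tolerance = 1e-8)
  expect_equal(fit$log_lik, -20 * log(2), tolerance = 1e-8)
})

test_that("fully concordant data are unidentifiable; concordant terms are dropped", {
  conc <- discordant_pairs(0, 0, 15)
  expect_error(suppressWarnings(fit_conditional_logistic(conc, "occupation_expose")),
               class = "famrisk_unidentifiable")

  # a term constant within every pair is dropped and leaves the rest unchanged
  cohort <- simulate_matched_cohort(cohort_config(n_pairs = 250, seed = 21,
                                                  shared_living_contact = TRUE))
  expect_warning(
    fit_with <- fit_conditional_logistic(cohort, c("smoking", "living_contact")),
    class = "famrisk_dropped_terms")
  fit_without <- fit_conditional_logistic(cohort, "smoking")
  expect_equal(fit_with$coefficients, fit_without$coefficients)
  expect_false("living_contact" %in% names(fit_with$blocks))
})

test_that("conditional fit agrees with the within-pair difference logistic oracle", {
  cohort <- simulate_matched_cohort(independent_config(n_pairs = 800, seed = 22))
  terms <- c("sex", "smoking", "occupation_expose")
  fit <- fit_conditional_logistic(cohort, terms)
  # oracle: 1:1 conditional likelihood == intercept-free logistic on
  # case-minus-control covariate differences with outcome 1
  X <- build_design(dplyr::arrange(cohort, pair_id, dplyr::desc(arm)), terms)
  d <- X[seq(1, nrow(X), 2), ] - X[seq(2, nrow(X), 2), ]
  orc <- glm(rep(1, nrow(d)) ~ 0 + d, family = binomial())
  expect_equal(unname(fit$coefficients$estimate), unname(coef(orc)),
               tolerance = 1e-5)
})

test_that("conditional fit recovers generating effects on synthetic pairs", {
  cfg <- independent_config(n_pairs = 4000, seed = 23)
  cohort <- simulate_matched_cohort(cfg)
  fit <- fit_conditional_logistic(cohort, risk_model_terms())
  truth <- cfg$true_betas[fit$coefficients$term]
  expect_true(all(abs(fit$coefficients$estimate - truth) <
                    3 * fit$coefficients$std_error))
})

test_that("age-stratified fits are consistent with the pooled estimate", {
  cfg <- independent_config(n_pairs = 3000, seed = 24)
  cohort <- simulate_matched_cohort(cfg)
  case_age <- dplyr::filter(cohort, arm == 1)[, c("pair_id", "age_group")]
  names(case_age)[2] <- "case_age"
  cohort <- dplyr::left_join(cohort, case_age, by = "pair_id")
  pooled <- fit_conditional_logistic(cohort, "smoking")
  young <- fit_conditional_logistic(dplyr::filter(cohort, case_age == 0), "smoking")
  old <- fit_conditional_logistic(dplyr::filter(cohort, case_age == 1), "smoking")
  # stratum estimates bracket-consistent: inverse-variance pooling of the
  # heavy-smoking effect agrees with the pooled fit within 3 pooled SEs
  b <- function(f) f$coefficients$estimate[f$coefficients$term == "smoking_heavy"]
  se <- function(f) f$coefficients$std_error[f$coefficients$term == "smoking_heavy"]
  w <- c(1 / se(young)^2, 1 / se(old)^2)
  meta <- sum(w * c(b(young), b(old))) / sum(w)
  expect_lt(abs(meta - b(pooled)), 3 * se(pooled))
})

test_that("adjusted OR tables carry reference rows and layout", {
  cohort <- simulate_matched_cohort(cohort_config(n_pairs = 250, seed = 25))
  fit <- fit_conditional_logistic(cohort, c("relatives_with_cancer", "sex"))
  tab <- adjusted_or_table(fit)
  # 3-level factor: reference plus two estimated rows
  rel <- tab[tab$term == "relatives_with_cancer", ]
  expect_equal(nrow(rel), 3)
  expect_equal(rel$or[1], 1)
  expect_true(all(is.na(rel$estimate[1])))
  expect_equal(rel$level, c("0", "1", "2+"))
  # derived OR/CI arithmetic
  est <- tab[!is.na(tab$estimate), ]
  expect_equal(est$or, exp(est$estimate))
  expect_equal(est$ci_high, exp(est$estimate + 1.96 * est$std_error))

  empty <- adjusted_or_table(structure(list(blocks = list(), converged = TRUE,
                                            coefficients = NULL),
                                       class = "famrisk_logit"))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("term", "level", "or") %in% names(empty)))
})

test_that("malformed pairings are rejected", {
  cohort <- simulate_matched_cohort(cohort_config(n_pairs = 5, seed = 1))
  expect_error(suppressWarnings(fit_conditional_logistic(cohort[-2, ], "sex")),
               class = "famrisk_unpaired")
})
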