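test_that("simulation honours the pairing contract and is seed-deterministic", {
  cfg <- cohort_config(n_pairs = 150, seed = 1)
  cohort <- simulate_matched_cohort(cfg)
  expect_equal(nrow(cohort), 300)
  expect_equal(sum(cohort$arm == 1), 150)
  counts <- dplyr::count(cohort, pair_id, arm)
  expect_true(all(counts$n == 1))
  expect_equal(nrow(counts), 300)
  expect_identical(cohort, simulate_matched_cohort(cfg))
  # a different seed gives different data
  expect_false(identical(cohort,
                         simulate_matched_cohort(cohort_config(n_pairs = 150, seed = 2))))
})

test_that("spousal structure: sex flip and shared living contact", {
  cohort <- simulate_matched_cohort(cohort_config(n_pairs = 200, seed = 3,
                                                  spouse_sex_flip_prob = 1,
                                                  shared_living_contact = TRUE))
  wide <- tidyr::pivot_wider(cohort, id_cols = "pair_id",
                             names_from = "arm",
                             values_from = c("sex", "living_contact"))
  expect_true(all(wide$sex_1 + wide$sex_0 == 1))
  expect_true(all(wide$living_contact_1 == wide$living_contact_0))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_pairs = 0), class = "famrisk_bad_config")
  expect_error(cohort_config(n_pairs = 10, q1 = 0.6), class = "famrisk_bad_config")
  expect_error(cohort_config(n_pairs = 10,
                             covariate_prevalences = within(default_prevalences(),
                                                            sex <- c(0.7, 0.7))),
               class = "famrisk_bad_config")
  expect_error(cohort_config(n_pairs = 10, true_betas = c(nonsense = 1)),
               class = "famrisk_bad_config")
  # implied disease probability above 0.5 somewhere signals a non-rare prior
  expect_error(cohort_config(n_pairs = 10, alpha_pop = -2),
               class = "famrisk_bad_config")
})

test_that("control-arm covariate frequencies converge to the prevalences", {
  cfg <- independent_config(n_pairs = 6000, seed = 9)
  controls <- dplyr::filter(simulate_matched_cohort(cfg), arm == 0)
  for (tm in covariate_terms()) {
    prev <- cfg$covariate_prevalences[[tm]]
    for (lev in seq_along(prev) - 1) {
      p_hat <- mean(controls[[tm]] == lev)
      se <- sqrt(prev[lev + 1] * (1 - prev[lev + 1]) / nrow(controls))
      expect_lt(abs(p_hat - prev[lev + 1]), 3 * se + 1e-3)
    }
  }
})

test_that("refitting the generating model recovers beta and the intercept offset", {
  cfg <- independent_config(n_pairs = 6000, seed = 17)
  cohort <- simulate_matched_cohort(cfg)
  fit <- fit_logistic_ml(cohort, covariate_terms())
  truth <- cfg$true_betas[fit$coefficients$term]
  expect_true(all(abs(fit$coefficients$estimate - truth) <
                    3 * fit$coefficients$std_error))
  # a' = alpha_pop + ln(n1 q0 / (n0 q1)) at the generator's implied incidence
  q1 <- implied_incidence(cfg)
  prior <- population_prior(cfg$n_pairs, cfg$n_pairs, q1)
  a <- correct_intercept(fit$intercept, prior)
  expect_lt(abs(a - cfg$alpha_pop), 3 * fit$intercept_se)
})

test_that("implied incidence equals the lattice expectation at a hand-checkable config", {
  # single active effect: incidence = sum_k P(smoking = k) expit(alpha + b_k)
  prev <- default_prevalences()
  cfg <- cohort_config(n_pairs = 5, alpha_pop = -7,
                       true_betas = c(smoking_heavy = 1.5),
                       covariate_prevalences = prev, seed = 1)
  hand <- sum(prev$smoking * plogis(-7 + c(0, 0, 1.5)))
  expect_equal(implied_incidence(cfg), hand)
})

test_that("subject CSV IO round-trips and validates codes", {
  cohort <- simulate_matched_cohort(cohort_config(n_pairs = 10, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_subjects(cohort, path)
  back <- read_subjects(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(cohort))

  bad <- cohort
  bad$smoking[3] <- 3L
  expect_error(validate_subjects(bad), "smoking.*row 3", class = "famrisk_bad_code")

  expect_error(validate_subjects(cohort[, -4]), class = "famrisk_missing_column")

  dup <- cohort
  dup$subject_id[2] <- dup$subject_id[1]
  expect_error(validate_subjects(dup), class = "famrisk_duplicate_id")
})

test_that("pairing audit reports cases lacking their control", {
  cohort <- simulate_matched_cohort(cohort_config(n_pairs = 6, seed = 5))
  orphaned <- cohort[-2, ] # drop pair 1's control
  expect_warning(report <- audit_pairing(orphaned), "1",
                 class = "famrisk_unpaired")
  expect_equal(report$pair_id, 1L)
  expect_equal(report$n_control, 0L)
})
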