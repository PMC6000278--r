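# shared fixtures built in code

# configuration with independent spouses: controls are i.i.d. draws from the
# population conditional on being disease-free, the setting in which the
# case-control intercept-offset identity and beta recovery are exact
independent_config <- function(n_pairs, seed, ...) {
  cohort_config(n_pairs = n_pairs, seed = seed,
                spouse_sex_flip_prob = 0, shared_living_contact = FALSE, ...)
}

# matched pairs with a single binary exposure and prescribed discordance:
# n10 pairs case-only exposed, n01 control-only exposed, n_conc concordant
discordant_pairs <- function(n10, n01, n_conc = 5) {
  n <- n10 + n01 + n_conc
  case_x <- c(rep(1L, n10), rep(0L, n01), rep(1L, n_conc))
  ctrl_x <- c(rep(0L, n10), rep(1L, n01), rep(1L, n_conc))
  tibble::tibble(
    subject_id = as.character(seq_len(2 * n)),
    pair_id = rep(seq_len(n), each = 2),
    arm = rep(c(1L, 0L), n),
    sex = 0L, age_group = 0L, smoking = 0L, lung_disease_history = 0L,
    living_contact = 0L, relatives_with_cancer = 0L,
    occupation_expose = as.integer(rbind(case_x, ctrl_x)))
}

# subject records expanded from a 2x2 exposure table (a exposed cases,
# b unexposed cases, c exposed controls, d unexposed controls)
records_from_2x2 <- function(a, b, c, d, term = "occupation_expose") {
  n <- a + b + c + d
  out <- tibble::tibble(
    subject_id = as.character(seq_len(n)),
    pair_id = seq_len(n),
    arm = rep(c(1L, 0L), c(a + b, c + d)),
    sex = 0L, age_group = 0L, smoking = 0L, lung_disease_history = 0L,
    living_contact = 0L, occupation_expose = 0L, relatives_with_cancer = 0L)
  out[[term]] <- rep(c(1L, 0L, 1L, 0L), c(a, b, c, d))
  out
}

zero_pattern <- function() {
  stats::setNames(rep(0, 7),
                  c("sex", "lung_disease_history", "occupation_expose",
                    "smoking_light", "smoking_heavy", "relatives_1",
                    "relatives_2plus"))
}

reference_corrected <- function() correct_model(reference_model(), reference_prior())
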