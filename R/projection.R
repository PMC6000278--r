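## Recalibration of the case-control intercept to a population incidence
## prior, and enumeration of covariate strata into the absolute-risk /
## relative-risk table.
##
## A case-control logistic fit estimates every slope consistently but its
## intercept a' reflects the sampling fractions, not population risk.
## Shifting by the log of the case/control sampling-rate ratio,
##   a = a' - ln(n1 * q0 / (n0 * q1)),
## yields an intercept on the population scale, where q1 is the population
## incidence and q0 = 1 - q1.

#' Population incidence prior for intercept recalibration
#'
#' @param n1 Number of cases in the study sample.
#' @param n0 Number of controls.
#' @param q1 Population disease incidence (prior probability of disease);
#'   defaults to the Chinese registry lung-cancer incidence 49.7 per 100,000.
#' @return A `famrisk_prior` list with `n1`, `n0`, `q1`, `q0`.
#' @export
#' @examples
#' population_prior(633, 565)
population_prior <- function(n1, n0, q1 = 49.7e-5) {
  if (n1 < 1 || n0 < 1) rlang::abort("n1 and n0 must be >= 1", class = "famrisk_bad_prior")
  if (!(q1 > 0 && q1 < 1)) {
    rlang::abort("q1 must lie strictly between 0 and 1", class = "famrisk_bad_prior")
  }
  q0 <- 1 - q1
  if (!(q1 < q0)) {
    rlang::abort("q1 must be below 0.5 (a rare-disease prior)", class = "famrisk_bad_prior")
  }
  structure(list(n1 = as.integer(n1), n0 = as.integer(n0), q1 = q1, q0 = q0),
            class = "famrisk_prior")
}

#' Recalibrate a case-control intercept to the population scale
#'
#' @param a_prime Raw case-control intercept.
#' @param prior A [population_prior()].
#' @return The corrected intercept `a_prime - log(n1 * q0 / (n0 * q1))`.
#' @export
#' @examples
#' correct_intercept(-0.867, population_prior(633, 565, 49.7e-5))
correct_intercept <- function(a_prime, prior) {
  stopifnot(inherits(prior, "famrisk_prior"))
  a_prime - log(prior$n1 * prior$q0 / (prior$n0 * prior$q1))
}

#' Attach a population prior to a fitted model
#'
#' @param model A `famrisk_logit` with a finite raw intercept (an
#'   unconditional fit).
#' @param prior A [population_prior()].
#' @return A `famrisk_corrected` object carrying the base model, the prior
#'   and the corrected intercept `a`.
#' @export
correct_model <- function(model, prior) {
  stopifnot(inherits(model, "famrisk_logit"))
  if (!is.finite(model$intercept)) {
    rlang::abort("model has no raw intercept to correct (conditional fit?)",
                 class = "famrisk_no_intercept")
  }
  structure(list(model = model, prior = prior,
                 a = correct_intercept(model$intercept, prior)),
            class = "famrisk_corrected")
}

#' @export
print.famrisk_corrected <- function(x, ...) {
  cat(sprintf("<famrisk_corrected: a' = %.4f -> a = %.4f (n1 = %d, n0 = %d, q1 = %g)>\n",
              x$model$intercept, x$a, x$prior$n1, x$prior$n0, x$prior$q1))
  print(x$model$coefficients, ...)
  invisible(x)
}

# dummy indicators of the risk-model pattern space, in the conventional
# stratum-table column order
pattern_columns <- function() {
  c("sex", "lung_disease_history", "occupation_expose",
    "smoking_light", "smoking_heavy", "relatives_1", "relatives_2plus")
}

validate_pattern <- function(pattern) {
  pattern <- unlist(pattern)
  miss <- setdiff(pattern_columns(), names(pattern))
  if (length(miss)) {
    rlang::abort(paste0("pattern lacks indicator(s): ", paste(miss, collapse = ", ")),
                 class = "famrisk_bad_pattern")
  }
  pattern <- pattern[pattern_columns()]
  if (!all(pattern %in% c(0, 1))) {
    rlang::abort("pattern indicators must be 0/1", class = "famrisk_bad_pattern")
  }
  if (pattern["smoking_light"] * pattern["smoking_heavy"] != 0 ||
      pattern["relatives_1"] * pattern["relatives_2plus"] != 0) {
    rlang::abort("mutually exclusive indicators are both set", class = "famrisk_bad_pattern")
  }
  pattern
}

model_betas <- function(model) {
  if (inherits(model, "famrisk_corrected")) model <- model$model
  cf <- stats::setNames(model$coefficients$estimate, model$coefficients$term)
  miss <- setdiff(pattern_columns(), names(cf))
  if (length(miss)) {
    rlang::abort(paste0("model lacks coefficient(s) for: ", paste(miss, collapse = ", ")),
                 class = "famrisk_bad_model")
  }
  cf[pattern_columns()]
}

#' Predicted disease probability for one covariate pattern
#'
#' Evaluates `logit = a + beta' pattern` under the corrected model and maps
#' it to a probability. `mode = "expit"` is the exact logistic inverse
#' `1 / (1 + exp(-logit))`; `mode = "odds_approx"` returns `exp(logit)`, the
#' small-probability approximation conventional in published stratum tables
#' (indistinguishable from expit when risks are rare, and the mode that
#' reproduces the reference table's printed values).
#'
#' @param pattern Named 0/1 vector (or one-row data frame) over
#'   [pattern_columns()].
#' @param model A `famrisk_corrected` model.
#' @param mode `"odds_approx"` or `"expit"`.
#' @return The predicted probability; warns if the odds approximation is
#'   evaluated where it degrades (result >= 0.1).
#' @export
#' @examples
#' ref <- correct_model(reference_model(), reference_prior())
#' p0 <- stratum_probability(
#'   c(sex = 0, lung_disease_history = 0, occupation_expose = 0,
#'     smoking_light = 0, smoking_heavy = 0, relatives_1 = 0,
#'     relatives_2plus = 0), ref)
#' relative_risk(p0, ref$prior$q1)
stratum_probability <- function(pattern, model,
                                mode = c("odds_approx", "expit")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "famrisk_corrected"))
  pattern <- validate_pattern(pattern)
  logit <- model$a + sum(model_betas(model) * pattern)
  if (mode == "expit") return(expit(logit))
  p <- exp(logit)
  if (p >= 0.1) {
    rlang::warn(sprintf("odds approximation degrading: exp(logit) = %.3f >= 0.1", p),
                class = "famrisk_approx_degrading")
  }
  p
}

#' Relative risk versus the population incidence
#'
#' @param p Predicted absolute probability.
#' @param q1 Population incidence.
#' @return `p / q1`.
#' @export
relative_risk <- function(p, q1) {
  if (any(q1 <= 0)) rlang::abort("q1 must be positive", class = "famrisk_bad_prior")
  p / q1
}

#' Risk-band label for a relative risk
#'
#' Conventional epidemiological strength-of-association bands: RR 1.0-1.1
#' none, 1.2-1.4 weak, 1.5-2.9 moderate, 3.0-9.0 strong, >= 10 very strong.
#' The published bands are not a partition; gaps (1.1-1.2, 9-10) map to the
#' nearest lower band, and RR below 1.0 is labelled `below-reference`.
#'
#' @param rr Positive relative risks (vectorised).
#' @return Ordered factor with levels `below-reference`, `none`, `weak`,
#'   `moderate`, `strong`, `very strong`.
#' @export
#' @examples
#' risk_band(c(0.38, 1.76, 63.08))
risk_band <- function(rr) {
  if (any(rr <= 0)) rlang::abort("rr must be positive", class = "famrisk_bad_rr")
  cut(rr, breaks = c(0, 1, 1.2, 1.5, 3, 10, Inf), right = FALSE,
      labels = c("below-reference", "none", "weak", "moderate", "strong",
                 "very strong"),
      ordered_result = TRUE)
}

full_pattern_grid <- function() {
  grid <- expand.grid(sex = 0:1, lung_disease_history = 0:1,
                      occupation_expose = 0:1, smoking = 0:2,
                      relatives_with_cancer = 0:2,
                      KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    sex = grid$sex,
    lung_disease_history = grid$lung_disease_history,
    occupation_expose = grid$occupation_expose,
    smoking_light = as.integer(grid$smoking == 1),
    smoking_heavy = as.integer(grid$smoking == 2),
    relatives_1 = as.integer(grid$relatives_with_cancer == 1),
    relatives_2plus = as.integer(grid$relatives_with_cancer == 2))
}

patterns_from_records <- function(records) {
  X <- build_design(records, risk_model_terms())
  tibble::as_tibble(as.data.frame(X))[pattern_columns()] |>
    dplyr::distinct()
}

#' Enumerate covariate strata into a risk table
#'
#' Builds the absolute-probability / relative-risk table over covariate
#' patterns of the risk model: either the patterns observed in `records`
#' (`grid = "observed"`) or all 72 legal patterns (2 sex x 2 lung history x
#' 2 occupation x 3 smoking x 3 relatives; `grid = "full"`). Rows are sorted
#' by ascending probability with ties broken by pattern lexicographic order.
#'
#' @param records Subject records (required for `grid = "observed"`).
#' @param model A `famrisk_corrected` model.
#' @param grid `"observed"` or `"full"`.
#' @param mode Probability mode, see [stratum_probability()].
#' @return A `famrisk_strata` tibble: `row`, the seven pattern indicators,
#'   `logit`, `probability`, `rr`, `band`.
#' @export
#' @examples
#' ref <- correct_model(reference_model(), reference_prior())
#' enumerate_strata(model = ref, grid = "full")
enumerate_strata <- function(records = NULL, model,
                             grid = c("observed", "full"),
                             mode = c("odds_approx", "expit")) {
  grid <- match.arg(grid)
  mode <- match.arg(mode)
  stopifnot(inherits(model, "famrisk_corrected"))
  pats <- if (grid == "full") {
    full_pattern_grid()
  } else {
    if (is.null(records)) {
      rlang::abort("records are required for grid = \"observed\"",
                   class = "famrisk_bad_config")
    }
    patterns_from_records(records)
  }
  beta <- model_betas(model)
  M <- as.matrix(pats[pattern_columns()])
  logit <- as.numeric(model$a + M %*% beta[pattern_columns()])
  probability <- if (mode == "expit") expit(logit) else exp(logit)
  if (mode == "odds_approx" && any(probability >= 0.1)) {
    rlang::warn("odds approximation degrading for some strata (p >= 0.1)",
                class = "famrisk_approx_degrading")
  }
  out <- dplyr::bind_cols(pats,
                          tibble::tibble(logit = logit,
                                         probability = probability,
                                         rr = relative_risk(probability, model$prior$q1))) |>
    dplyr::mutate(band = risk_band(.data$rr)) |>
    dplyr::arrange(.data$probability,
                   dplyr::across(dplyr::all_of(pattern_columns()))) |>
    dplyr::mutate(row = dplyr::row_number(), .before = 1)
  attr(out, "mode") <- mode
  attr(out, "q1") <- model$prior$q1
  class(out) <- c("famrisk_strata", class(out))
  out
}
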