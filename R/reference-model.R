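## Bundled reference values: the published familial lung-cancer risk model
## (coefficients, study sizes, incidence prior) and the printed contingency
## and classification tables of the reference case-control study (633 lung
## cancer probands, 565 spouse controls), shipped as plain CSVs under
## inst/extdata.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "famrisk")
  if (p == "") rlang::abort(paste0("bundled fixture not found: ", file))
  p
}

read_ref <- function(file) readr::read_csv(ref_path(file), show_col_types = FALSE)

#' Reference risk-model coefficients as a named vector
#'
#' Dummy-scale log-odds effects of the published five-term model (sex,
#' smoking light/heavy, lung-disease history, occupational exposure, 1 and
#' >= 2 affected relatives), without the intercept. Used as the default
#' `true_betas` of [cohort_config()].
#'
#' @return Named numeric vector.
#' @export
reference_betas <- function() {
  cf <- read_ref("reference_coefficients.csv")
  cf <- cf[cf$term != "(intercept)", ]
  stats::setNames(cf$estimate, cf$term)
}

#' The published reference risk model as a fitted-model object
#'
#' Reconstructs a `famrisk_logit` from the published coefficient table
#' (estimates, standard errors and the raw case-control intercept
#' a' = -0.867). The covariance matrix is diagonal — printed tables carry no
#' covariances — which is sufficient for per-term Wald statistics and risk
#' projection.
#'
#' @return A `famrisk_logit`.
#' @export
#' @examples
#' reference_model()
reference_model <- function() {
  cf <- read_ref("reference_coefficients.csv")
  icpt <- cf[cf$term == "(intercept)", ]
  cf <- cf[cf$term != "(intercept)", ]
  B <- stats::setNames(cf$estimate, cf$term)
  SE <- stats::setNames(cf$std_error, cf$term)
  V <- diag(c(icpt$std_error, SE)^2)
  dimnames(V) <- list(c("(intercept)", names(B)), c("(intercept)", names(B)))
  new_famrisk_logit(
    coefficients = coefficient_table(B, SE),
    intercept = icpt$estimate, intercept_se = icpt$std_error, vcov = V,
    log_lik = NA_real_, n = 633L + 565L, converged = TRUE,
    type = "unconditional", blocks = famrisk_dummies[risk_model_terms()])
}

#' The reference study's population prior
#'
#' 633 cases, 565 controls, and the registry lung-cancer incidence of 49.7
#' per 100,000 as the population prior.
#'
#' @return A [population_prior()].
#' @export
reference_prior <- function() {
  pr <- read_ref("reference_prior.csv")
  population_prior(pr$n1, pr$n0, pr$q1)
}

#' Printed tables bundled with the package
#'
#' Machine-readable copies of the reference study's printed tables:
#' `"balance"` (case/control counts per balance characteristic), `"or"`
#' (labelled 2x2 tables behind the crude odds ratios, with printed OR/CI),
#' `"classification"` (the overall observed-by-predicted table), and
#' `"highrisk"` (per-stratum forecast and fact counts of the RR > 10
#' subgroup).
#'
#' @param which One of `"balance"`, `"or"`, `"classification"`, `"highrisk"`.
#' @return A tibble.
#' @export
reference_counts <- function(which = c("balance", "or", "classification", "highrisk")) {
  which <- match.arg(which)
  read_ref(switch(which,
                  balance = "reference_balance_counts.csv",
                  or = "reference_or_tables.csv",
                  classification = "reference_classification_overall.csv",
                  highrisk = "reference_highrisk_strata.csv"))
}
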