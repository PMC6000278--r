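## Matched-pair (1:1) conditional logistic regression. The pair is the
## matching stratum; covariates such as sex and smoking enter as model terms.
## Fitting is delegated to the exact conditional likelihood of
## survival::clogit; identifiability, discordance screening and error
## surfacing live here.

#' Fit a 1:1 conditional logistic regression on matched pairs
#'
#' Maximises the matched-pair conditional likelihood
#' `prod exp(b'x_case) / (exp(b'x_case) + exp(b'x_control))`, which has no
#' intercept — pair-level nuisance effects are conditioned away. Terms with
#' no within-pair discordance carry no information and are dropped with a
#' warning; if no term is discordant in any pair, the model is
#' unidentifiable and an error is raised.
#'
#' @param pairs Data frame of subject records with `pair_id` and `arm`; each
#'   pair must link exactly one case and one control.
#' @param terms Covariate terms ([covariate_terms()]).
#' @param tol Convergence tolerance.
#' @param max_iter Iteration cap.
#' @param conf_z Normal quantile for the intervals.
#' @return A `famrisk_logit` object with `intercept = NA`.
#' @export
#' @examples
#' cohort <- simulate_matched_cohort(cohort_config(n_pairs = 300, seed = 2))
#' fit <- fit_conditional_logistic(cohort, c("smoking", "occupation_expose"))
#' adjusted_or_table(fit)
fit_conditional_logistic <- function(pairs, terms, tol = 1e-8, max_iter = 50,
                                     conf_z = 1.96) {
  stopifnot(is.data.frame(pairs), all(c("pair_id", "arm") %in% names(pairs)))
  bad <- audit_pairing(pairs)
  if (nrow(bad)) {
    rlang::abort("pairs must each link exactly one case and one control",
                 class = "famrisk_unpaired")
  }
  pairs <- dplyr::arrange(pairs, .data$pair_id, dplyr::desc(.data$arm))
  X <- build_design(pairs, terms)
  blocks <- attr(X, "blocks")

  # within-pair differences (case minus control) reveal which terms carry
  # conditional information
  case_rows <- pairs$arm == 1
  diffs <- X[case_rows, , drop = FALSE] - X[!case_rows, , drop = FALSE]
  informative <- vapply(blocks, function(cols) {
    any(diffs[, cols, drop = FALSE] != 0)
  }, logical(1))
  if (!any(informative)) {
    rlang::abort("all pairs are concordant on every term; model unidentifiable",
                 class = "famrisk_unidentifiable")
  }
  if (any(!informative)) {
    rlang::warn(paste0("dropping term(s) with no within-pair discordance: ",
                       paste(names(blocks)[!informative], collapse = ", ")),
                class = "famrisk_dropped_terms")
    blocks <- blocks[informative]
    X <- X[, unlist(blocks, use.names = FALSE), drop = FALSE]
  }

  dat <- data.frame(..y = pairs$arm, ..pair = pairs$pair_id, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "..y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + "),
    "+ survival::strata(..pair)"))
  fit <- tryCatch(
    survival::clogit(fml, data = dat, method = "exact",
                     iter.max = max_iter, eps = tol),
    error = function(e) rlang::abort(paste0("conditional fit failed: ", conditionMessage(e)),
                                     class = "famrisk_no_convergence", parent = e))
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  if (any(!is.finite(cf)) || max(abs(cf)) > 15) {
    rlang::abort("separation detected: a coefficient diverges",
                 class = "famrisk_separation", last_coefficients = cf)
  }
  names(cf) <- names(se) <- colnames(X)
  new_famrisk_logit(
    coefficients = coefficient_table(cf, se, conf_z),
    intercept = NA_real_, intercept_se = NA_real_, vcov = V,
    log_lik = as.numeric(fit$loglik[2]), n = sum(case_rows),
    converged = TRUE, type = "conditional", blocks = blocks,
    subclass = "famrisk_cond_logit")
}

level_labels <- list(
  sex = c("female", "male"),
  age_group = c("<50", ">=50"),
  smoking = c("never", "light", "heavy"),
  lung_disease_history = c("no", "yes"),
  living_contact = c("no", "yes"),
  occupation_expose = c("no", "yes"),
  relatives_with_cancer = c("0", "1", "2+")
)

#' Per-term adjusted odds-ratio table
#'
#' Formats a fitted model as the familiar adjusted-OR listing: one row per
#' non-reference level with OR and CI, preceded by the reference level with
#' OR printed as 1.00.
#'
#' @param model A `famrisk_logit`.
#' @param conf_z Normal quantile used when re-deriving the intervals.
#' @return Tibble: `term`, `level`, `estimate`, `std_error`, `or`, `ci_low`,
#'   `ci_high`, `p_value` (reference rows carry `or = 1` and `NA` elsewhere).
#' @export
adjusted_or_table <- function(model, conf_z = 1.96) {
  stopifnot(inherits(model, "famrisk_logit"))
  if (!isTRUE(model$converged)) {
    rlang::abort("model did not converge", class = "famrisk_no_convergence")
  }
  empty <- tibble::tibble(term = character(), level = character(),
                          estimate = double(), std_error = double(),
                          or = double(), ci_low = double(), ci_high = double(),
                          p_value = double())
  if (!length(model$blocks)) return(empty)
  rows <- purrr::map(names(model$blocks), function(tm) {
    cols <- model$blocks[[tm]]
    labs <- level_labels[[tm]]
    cf <- model$coefficients[match(cols, model$coefficients$term), ]
    ref <- tibble::tibble(term = tm, level = labs[1], estimate = NA_real_,
                          std_error = NA_real_, or = 1, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_)
    est <- tibble::tibble(term = tm, level = labs[-1][seq_along(cols)],
                          estimate = cf$estimate, std_error = cf$std_error,
                          or = cf$or, ci_low = cf$ci_low, ci_high = cf$ci_high,
                          p_value = cf$p_value)
    dplyr::bind_rows(ref, est)
  })
  dplyr::bind_rows(empty, rows)
}
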