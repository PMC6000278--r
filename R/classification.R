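## Cutoff classification of fitted probabilities and the observed-by-
## predicted validation tables. Classification always uses the raw
## case-control fit (intercept a'): corrected population probabilities are
## all far below 0.5 and would classify everyone as a control.

#' Classify a fitted probability at a cutoff
#'
#' Strict rule: below the cutoff is `control`, above is `case`, exactly at
#' the cutoff the subject is left `unclassified`.
#'
#' @param p Probabilities in \[0, 1\] (vectorised).
#' @param cutoff Classification cutoff, default 0.5.
#' @return Factor with levels `control`, `case`, `unclassified`.
#' @export
#' @examples
#' classify_probability(c(0.3, 0.7, 0.5))
classify_probability <- function(p, cutoff = 0.5) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("probabilities must lie in [0, 1]", class = "famrisk_bad_probability")
  }
  out <- ifelse(p < cutoff, "control", ifelse(p > cutoff, "case", "unclassified"))
  factor(out, levels = c("control", "case", "unclassified"))
}

new_classification <- function(counts, unclassified, cutoff) {
  n_ctrl <- sum(counts["control", ])
  n_case <- sum(counts["case", ])
  n_classified <- n_ctrl + n_case
  correct <- counts["control", "control"] + counts["case", "case"]
  structure(
    list(counts = counts, unclassified = unclassified, cutoff = cutoff,
         n = n_classified + unclassified,
         control_pct = if (n_ctrl) 100 * counts["control", "control"] / n_ctrl else NA_real_,
         case_pct = if (n_case) 100 * counts["case", "case"] / n_case else NA_real_,
         overall_pct = if (n_classified) 100 * correct / n_classified else NA_real_),
    class = "famrisk_classification")
}

#' Observed-by-predicted classification table
#'
#' Cross-tabulates true arms against cutoff-classified fitted probabilities
#' and computes per-class and overall percent correct. Subjects exactly at
#' the cutoff are excluded from the percent-correct denominators and
#' reported separately as unclassified.
#'
#' @param true_arms 0/1 vector of observed arms (1 = case).
#' @param fitted_probs Fitted probabilities, same length.
#' @param cutoff Classification cutoff.
#' @return A `famrisk_classification` object.
#' @export
#' @examples
#' classification_table(c(0, 0, 1, 1), c(0.2, 0.7, 0.8, 0.9))
classification_table <- function(true_arms, fitted_probs, cutoff = 0.5) {
  if (length(true_arms) != length(fitted_probs)) {
    rlang::abort("true_arms and fitted_probs must have equal length",
                 class = "famrisk_length_mismatch")
  }
  if (!all(true_arms %in% 0:1)) {
    rlang::abort("true_arms must be 0/1", class = "famrisk_bad_code")
  }
  pred <- classify_probability(fitted_probs, cutoff)
  obs <- factor(ifelse(true_arms == 1, "case", "control"),
                levels = c("control", "case"))
  unclassified <- sum(pred == "unclassified")
  keep <- pred != "unclassified"
  counts <- table(observed = obs[keep], predicted = droplevels(pred[keep], exclude = "unclassified"))
  counts <- as.matrix(counts)
  full <- matrix(0L, 2, 2, dimnames = list(observed = c("control", "case"),
                                           predicted = c("control", "case")))
  full[rownames(counts), colnames(counts)] <- counts
  new_classification(full, unclassified, cutoff)
}

#' @export
print.famrisk_classification <- function(x, ...) {
  cat(sprintf("<famrisk_classification: cutoff %.3f, n = %d (%d unclassified)>\n",
              x$cutoff, x$n, x$unclassified))
  print(x$counts)
  cat(sprintf("percent correct: control %.1f, case %.1f, overall %.1f\n",
              x$control_pct, x$case_pct, x$overall_pct))
  invisible(x)
}

#' Classification within the high-relative-risk subgroup
#'
#' Restricts subjects to covariate patterns whose corrected-model relative
#' risk exceeds `rr_threshold` (subgroup membership is by stratum, not by
#' individual probability) and tabulates classification there. The
#' probabilities classified are from the UNCORRECTED case-control fit
#' (intercept a'), as in the overall table.
#'
#' @param records Subject records with `arm` and the risk-model covariates.
#' @param model A `famrisk_corrected` model.
#' @param strata Optional precomputed [enumerate_strata()] table for the same
#'   model (recomputed on the observed grid when omitted).
#' @param rr_threshold Relative-risk threshold, default 10.
#' @param cutoff Classification cutoff.
#' @return A `famrisk_classification`; empty subgroup returns an all-zero
#'   table with a warning.
#' @export
high_risk_subgroup_eval <- function(records, model, strata = NULL,
                                    rr_threshold = 10, cutoff = 0.5) {
  stopifnot(inherits(model, "famrisk_corrected"))
  if (is.null(strata)) {
    strata <- enumerate_strata(records, model, grid = "observed")
  }
  high <- dplyr::filter(tibble::as_tibble(strata), .data$rr > rr_threshold)
  X <- build_design(records, risk_model_terms())
  pat_key <- apply(X[, pattern_columns(), drop = FALSE], 1, paste, collapse = "")
  high_key <- apply(as.matrix(high[pattern_columns()]), 1, paste, collapse = "")
  member <- pat_key %in% high_key
  if (!any(member)) {
    rlang::warn("no subjects fall in the high-risk subgroup", class = "famrisk_empty_subgroup")
    empty <- matrix(0L, 2, 2, dimnames = list(observed = c("control", "case"),
                                              predicted = c("control", "case")))
    return(new_classification(empty, 0L, cutoff))
  }
  sub <- records[member, , drop = FALSE]
  probs <- predict_probability(model$model, sub)
  classification_table(sub$arm, probs, cutoff)
}

#' Predicted probabilities from a fitted (uncorrected) model
#'
#' Evaluates `expit(a' + beta'x)` per subject — the in-sample case-control
#' probability used for classification.
#'
#' @param model A `famrisk_logit` with a finite intercept.
#' @param records Subject records.
#' @return Numeric vector of probabilities.
#' @export
predict_probability <- function(model, records) {
  stopifnot(inherits(model, "famrisk_logit"))
  if (!is.finite(model$intercept)) {
    rlang::abort("model has no intercept; cannot compute absolute probabilities",
                 class = "famrisk_no_intercept")
  }
  terms <- names(model$blocks)
  X <- build_design(records, terms)
  cf <- stats::setNames(model$coefficients$estimate, model$coefficients$term)
  expit(as.numeric(model$intercept + X %*% cf[colnames(X)]))
}
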