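## Forward stepwise logistic regression: candidates enter on the Rao score
## test (smallest p < p_enter) and included terms are removed when their
## likelihood-ratio p exceeds p_remove. Multi-level factors move as blocks
## (df = levels - 1).

#' Forward stepwise logistic model selection
#'
#' Iterates: fit the current unconditional model; among excluded candidates,
#' enter the one with the smallest score-test p-value if below `p_enter`;
#' after every entry, remove any included term whose likelihood-ratio
#' p-value exceeds `p_remove` (worst first); stop when no entry or removal
#' changes the model. A repeated model state stops the run with a cycling
#' warning recorded in the trace.
#'
#' @param records Data frame of subject records with an `arm` column.
#' @param candidate_terms Covariate terms eligible for selection.
#' @param p_enter Score-test entry threshold.
#' @param p_remove Likelihood-ratio removal threshold.
#' @param tol,max_iter Passed to [fit_logistic_ml()].
#' @return A `famrisk_stepwise` object: `model` (final `famrisk_logit`) and
#'   `trace` (tibble of steps: action, term, statistic, df, p, log-lik).
#' @export
#' @examples
#' cohort <- simulate_matched_cohort(cohort_config(n_pairs = 400, seed = 3))
#' sel <- forward_stepwise(cohort, c("sex", "smoking", "age_group"))
#' sel$trace
forward_stepwise <- function(records, candidate_terms, p_enter = 0.05,
                             p_remove = 0.10, tol = 1e-8, max_iter = 50) {
  stopifnot(is.data.frame(records), "arm" %in% names(records))
  bad <- setdiff(candidate_terms, covariate_terms())
  if (length(bad)) {
    rlang::abort(paste0("unknown candidate term(s): ", paste(bad, collapse = ", ")),
                 class = "famrisk_bad_term")
  }
  trace <- tibble::tibble(step = integer(), action = character(),
                          term = character(), statistic = double(),
                          df = integer(), p_value = double(),
                          log_lik = double(), note = character())
  included <- character()
  visited <- character()
  step_i <- 0L
  fit <- fit_logistic_ml(records, included, tol = tol, max_iter = max_iter)
  X_all <- build_design(records, union(candidate_terms, character()))
  keep <- stats::complete.cases(records$arm) &
    (if (ncol(X_all)) stats::complete.cases(X_all) else TRUE)
  # listwise exclusion must be consistent across candidate models, so the
  # score tests and refits all use the complete-case subset
  records <- records[keep, , drop = FALSE]
  fit <- fit_logistic_ml(records, included, tol = tol, max_iter = max_iter)

  repeat {
    state <- paste(sort(included), collapse = "|")
    if (state %in% visited) {
      trace <- dplyr::add_row(trace, step = step_i, action = "stop",
                              term = NA_character_, statistic = NA_real_,
                              df = NA_integer_, p_value = NA_real_,
                              log_lik = fit$log_lik,
                              note = "cycling detected; stopped")
      rlang::warn("stepwise selection revisited a model state; stopping",
                  class = "famrisk_stepwise_cycle")
      break
    }
    visited <- c(visited, state)

    pool <- setdiff(candidate_terms, included)
    if (!length(pool)) break
    scores <- purrr::map(pool, function(tm) {
      Xn <- build_design(records, tm)
      score_test_add(fit, Xn)
    })
    p_scores <- vapply(scores, `[[`, numeric(1), "p_value")
    best <- which.min(p_scores)
    if (!length(best) || p_scores[best] >= p_enter) break

    step_i <- step_i + 1L
    included <- c(included, pool[best])
    fit <- fit_logistic_ml(records, included, tol = tol, max_iter = max_iter)
    trace <- dplyr::add_row(trace, step = step_i, action = "enter",
                            term = pool[best],
                            statistic = scores[[best]]$statistic,
                            df = as.integer(scores[[best]]$df),
                            p_value = p_scores[best], log_lik = fit$log_lik,
                            note = NA_character_)

    # backward removal sweep by likelihood ratio
    repeat {
      if (!length(included)) break
      lrs <- purrr::map(included, function(tm) {
        reduced <- fit_logistic_ml(records, setdiff(included, tm),
                                   tol = tol, max_iter = max_iter)
        stat <- 2 * (fit$log_lik - reduced$log_lik)
        df <- length(famrisk_dummies[[tm]])
        list(statistic = stat, df = df,
             p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
      })
      p_lr <- vapply(lrs, `[[`, numeric(1), "p_value")
      worst <- which.max(p_lr)
      if (p_lr[worst] <= p_remove) break
      step_i <- step_i + 1L
      gone <- included[worst]
      included <- setdiff(included, gone)
      fit <- fit_logistic_ml(records, included, tol = tol, max_iter = max_iter)
      trace <- dplyr::add_row(trace, step = step_i, action = "remove",
                              term = gone,
                              statistic = lrs[[worst]]$statistic,
                              df = as.integer(lrs[[worst]]$df),
                              p_value = p_lr[worst], log_lik = fit$log_lik,
                              note = NA_character_)
    }
  }
  structure(list(model = fit, trace = trace, included = included,
                 p_enter = p_enter, p_remove = p_remove),
            class = "famrisk_stepwise")
}

#' @export
print.famrisk_stepwise <- function(x, ...) {
  cat(sprintf("<famrisk_stepwise: %d step(s), final terms: %s>\n",
              nrow(x$trace),
              if (length(x$included)) paste(x$included, collapse = ", ") else "(none)"))
  print(x$trace, ...)
  invisible(x)
}
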