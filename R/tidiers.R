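## broom-style tidy()/glance() methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted logistic model
#'
#' @param x A `famrisk_logit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (including the intercept for
#'   unconditional fits): `term`, `estimate`, `std_error`, `wald`,
#'   `p_value`, `or`, `ci_low`, `ci_high`.
#' @export
tidy.famrisk_logit <- function(x, ...) {
  out <- x$coefficients
  if (is.finite(x$intercept)) {
    out <- dplyr::bind_rows(
      coefficient_table(stats::setNames(x$intercept, "(intercept)"),
                        stats::setNames(x$intercept_se, "(intercept)")),
      out)
  }
  out
}

#' @rdname tidy.famrisk_logit
#' @export
glance.famrisk_logit <- function(x, ...) {
  tibble::tibble(type = x$type, n = x$n, log_lik = x$log_lik,
                 n_terms = length(x$blocks), converged = x$converged,
                 intercept = x$intercept)
}

#' Tidy a stepwise selection run
#'
#' @param x A `famrisk_stepwise`.
#' @param ... Unused.
#' @return The step trace tibble (`tidy`) or a one-row summary (`glance`).
#' @export
tidy.famrisk_stepwise <- function(x, ...) x$trace

#' @rdname tidy.famrisk_stepwise
#' @export
glance.famrisk_stepwise <- function(x, ...) {
  tibble::tibble(n_steps = nrow(x$trace),
                 n_selected = length(x$included),
                 selected = paste(sort(x$included), collapse = ","),
                 p_enter = x$p_enter, p_remove = x$p_remove,
                 log_lik = x$model$log_lik)
}

#' Tidy a corrected model
#'
#' @param x A `famrisk_corrected`.
#' @param ... Unused.
#' @return Coefficients of the base model with the corrected intercept row
#'   (`tidy`), or the prior and intercepts (`glance`).
#' @export
tidy.famrisk_corrected <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "(corrected intercept)", estimate = x$a),
    x$model$coefficients)
}

#' @rdname tidy.famrisk_corrected
#' @export
glance.famrisk_corrected <- function(x, ...) {
  tibble::tibble(a_prime = x$model$intercept, a = x$a,
                 n1 = x$prior$n1, n0 = x$prior$n0,
                 q1 = x$prior$q1, q0 = x$prior$q0)
}

#' Tidy a classification table
#'
#' @param x A `famrisk_classification`.
#' @param ... Unused.
#' @return Long counts per observed/predicted cell (`tidy`) or the percent
#'   summary (`glance`).
#' @export
tidy.famrisk_classification <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$counts))) |>
    dplyr::rename(count = "Freq") |>
    dplyr::mutate(dplyr::across(c("observed", "predicted"), as.character))
}

#' @rdname tidy.famrisk_classification
#' @export
glance.famrisk_classification <- function(x, ...) {
  tibble::tibble(overall_pct = x$overall_pct, control_pct = x$control_pct,
                 case_pct = x$case_pct, n = x$n,
                 unclassified = x$unclassified, cutoff = x$cutoff)
}
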