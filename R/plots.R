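## ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a fitted logistic model
#'
#' Odds ratios with confidence intervals per model term, on a log scale.
#'
#' @param object A `famrisk_logit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.famrisk_logit <- function(object, ...) {
  df <- object$coefficients
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or,
                                   y = stats::reorder(.data$term, .data$or))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  title = sprintf("%s logistic fit (n = %d)", object$type, object$n)) +
    ggplot2::theme_minimal()
}

#' Risk-ladder plot of enumerated strata
#'
#' Relative risk per covariate stratum (ascending), coloured by risk band,
#' with the RR = 1 and RR = 10 guides.
#'
#' @param object A `famrisk_strata` tibble from [enumerate_strata()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.famrisk_strata <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$rr,
                                   colour = .data$band)) +
    ggplot2::geom_hline(yintercept = c(1, 10), linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "stratum (ascending risk)",
                  y = "relative risk vs population (log scale)",
                  colour = "band") +
    ggplot2::theme_minimal()
}

#' Log-likelihood trajectory of a stepwise run
#'
#' @param object A `famrisk_stepwise`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.famrisk_stepwise <- function(object, ...) {
  df <- object$trace
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$log_lik)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$action), size = 2) +
    ggplot2::labs(x = "step", y = "model log-likelihood", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Bar display of a classification table
#'
#' @param object A `famrisk_classification`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.famrisk_classification <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$count,
                                   fill = .data$predicted)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "observed arm", y = "subjects", fill = "predicted",
                  title = sprintf("overall %.1f%% correct (cutoff %.2f)",
                                  object$overall_pct, object$cutoff)) +
    ggplot2::theme_minimal()
}
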