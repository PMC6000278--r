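## Unconditional maximum-likelihood logistic regression and the Wald/OR
## arithmetic shared by the model tables.

#' Wald statistics and odds ratios from coefficients
#'
#' `wald = (B / SE)^2` with a chi-square (df = 1) p-value, `OR = exp(B)` and
#' `CI = exp(B +/- z * SE)`. Vectorised.
#'
#' @param B Log-odds coefficients.
#' @param SE Positive standard errors.
#' @param conf_z Normal quantile for the interval (1.96 for 95%).
#' @return Tibble: `wald`, `p_value`, `or`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' wald_and_or(1.545, 0.211)
wald_and_or <- function(B, SE, conf_z = 1.96) {
  if (any(SE <= 0)) rlang::abort("SE must be positive", class = "famrisk_bad_se")
  w <- (B / SE)^2
  tibble::tibble(
    wald = w,
    p_value = stats::pchisq(w, df = 1, lower.tail = FALSE),
    or = exp(B),
    ci_low = exp(B - conf_z * SE),
    ci_high = exp(B + conf_z * SE))
}

# assemble the shared fitted-model container
new_famrisk_logit <- function(coefficients, intercept, intercept_se, vcov,
                              log_lik, n, converged, type, blocks,
                              subclass = character()) {
  structure(
    list(coefficients = coefficients, intercept = intercept,
         intercept_se = intercept_se, vcov = vcov, log_lik = log_lik,
         n = n, converged = converged, type = type, blocks = blocks),
    class = c(subclass, "famrisk_logit"))
}

coefficient_table <- function(B, SE, conf_z = 1.96) {
  dplyr::bind_cols(tibble::tibble(term = names(B), estimate = unname(B),
                                  std_error = unname(SE)),
                   wald_and_or(unname(B), unname(SE), conf_z))
}

#' @export
print.famrisk_logit <- function(x, ...) {
  cat(sprintf("<famrisk_logit: %s, n = %d, logLik = %.3f%s>\n",
              x$type, x$n, x$log_lik,
              if (is.na(x$intercept)) "" else sprintf(", intercept a' = %.4f", x$intercept)))
  print(x$coefficients, ...)
  invisible(x)
}

#' Fit an unconditional logistic regression by maximum likelihood
#'
#' Case-control (arm 1/0) logistic model over treatment-coded covariate
#' terms, fitted by iteratively reweighted least squares with standard errors
#' from the inverse observed information. Multi-level terms expand to dummy
#' indicators with level 0 as reference. Records with missing values on the
#' outcome or any requested term are excluded listwise.
#'
#' @param records Data frame of subject records with an `arm` column.
#' @param terms Covariate terms to include ([covariate_terms()]); may be
#'   empty for the intercept-only model.
#' @param tol Convergence tolerance on the deviance.
#' @param max_iter Iteration cap.
#' @param conf_z Normal quantile for the intervals.
#' @return A `famrisk_logit` object; its raw case-control intercept is the
#'   `intercept` field (a-prime), not interpretable as a population risk
#'   until recalibrated with [correct_model()].
#' @export
#' @examples
#' cohort <- simulate_matched_cohort(cohort_config(n_pairs = 200, seed = 1))
#' fit <- fit_logistic_ml(cohort, c("sex", "smoking"))
#' tidy(fit)
fit_logistic_ml <- function(records, terms, tol = 1e-8, max_iter = 50,
                            conf_z = 1.96) {
  stopifnot(is.data.frame(records), "arm" %in% names(records))
  X <- build_design(records, terms)
  blocks <- attr(X, "blocks")
  keep <- stats::complete.cases(records$arm) &
    (if (ncol(X)) stats::complete.cases(X) else TRUE)
  y <- as.numeric(records$arm[keep])
  X <- X[keep, , drop = FALSE]
  if (length(unique(y)) < 2L) {
    rlang::abort("outcome is constant; both classes are required",
                 class = "famrisk_constant_outcome")
  }
  Xfull <- cbind(`(intercept)` = 1, X)
  qr_x <- qr(Xfull)
  if (qr_x$rank < ncol(Xfull)) {
    dropped <- colnames(Xfull)[qr_x$pivot[(qr_x$rank + 1):ncol(Xfull)]]
    rlang::abort(paste0("design matrix is rank deficient; collinear column(s): ",
                        paste(dropped, collapse = ", ")),
                 class = "famrisk_rank_deficient")
  }
  dat <- data.frame(..y = y, X, check.names = FALSE)
  fml <- if (ncol(X)) {
    stats::reformulate(sprintf("`%s`", colnames(X)), response = "..y")
  } else {
    ..y ~ 1
  }
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(),
               data = dat,
               control = stats::glm.control(epsilon = tol, maxit = max_iter)))
  if (!fit$converged) {
    rlang::abort("logistic fit did not converge within max_iter iterations",
                 class = "famrisk_no_convergence",
                 last_coefficients = stats::coef(fit))
  }
  cf <- stats::coef(fit)
  if (max(abs(cf[-1]), 0) > 15) {
    rlang::abort("complete or quasi-complete separation detected (diverging coefficient)",
                 class = "famrisk_separation", last_coefficients = cf)
  }
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  names(cf)[1] <- names(se)[1] <- "(intercept)"
  out <- new_famrisk_logit(
    coefficients = coefficient_table(cf[-1], se[-1], conf_z),
    intercept = unname(cf[1]), intercept_se = unname(se[1]),
    vcov = V, log_lik = as.numeric(stats::logLik(fit)),
    n = length(y), converged = TRUE, type = "unconditional",
    blocks = blocks, subclass = "famrisk_uncond_logit")
  out$glm_fit <- fit
  out$design <- X
  out$response <- y
  out
}

# Rao score test for adding a block of columns to a fitted unconditional
# model: S = U' (I_nn - I_no I_oo^-1 I_on)^-1 U evaluated at the null fit.
score_test_add <- function(fit, X_new) {
  stopifnot(inherits(fit, "famrisk_uncond_logit"))
  X_new <- as.matrix(X_new)
  mu <- stats::fitted(fit$glm_fit)
  w <- mu * (1 - mu)
  X0 <- cbind(1, fit$design)
  U <- crossprod(X_new, fit$response - mu)
  I_nn <- crossprod(X_new * w, X_new)
  I_no <- crossprod(X_new * w, X0)
  I_oo <- crossprod(X0 * w, X0)
  V <- I_nn - I_no %*% solve(I_oo, t(I_no))
  stat <- as.numeric(crossprod(U, solve(V, U)))
  df <- ncol(X_new)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
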