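## Crude (unadjusted) contingency-table statistics: Woolf odds ratios,
## Pearson chi-square, Fisher exact and the pooled two-sample t-test.

as_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    # rows = arm (case, control), cols = exposure (exposed, unexposed)
    return(c(a = a[1, 1], b = a[1, 2], c = a[2, 1], d = a[2, 2]))
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4L || anyNA(cells)) {
    rlang::abort("need four cell counts a, b, c, d", class = "famrisk_bad_table")
  }
  if (any(cells < 0)) rlang::abort("counts must be non-negative", class = "famrisk_bad_table")
  cells
}

#' Woolf odds ratio with confidence interval
#'
#' Crude odds ratio `ad / bc` from a 2x2 table with the Woolf logit-scale
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)` and interval
#' `exp(log OR +/- z * se)`. Cell labels: `a` exposed cases, `b` unexposed
#' cases, `c` exposed controls, `d` unexposed controls.
#'
#' Zero cells are an error (the estimate would be degenerate); set
#' `haldane = TRUE` to opt in to the Haldane-Anscombe +0.5 correction — it is
#' never applied silently.
#'
#' @param a,b,c,d Cell counts, or a 2x2 matrix in `a`.
#' @param conf_z Normal quantile for the interval (1.96 for 95%).
#' @param haldane Add 0.5 to every cell before estimating.
#' @return One-row tibble: `or`, `ci_low`, `ci_high`, `log_or`, `se_log_or`.
#' @export
#' @examples
#' odds_ratio_woolf(201, 432, 127, 438)
odds_ratio_woolf <- function(a, b = NULL, c = NULL, d = NULL,
                             conf_z = 1.96, haldane = FALSE) {
  cells <- as_2x2(a, b, c, d)
  if (haldane) cells <- cells + 0.5
  zero <- names(cells)[cells == 0]
  if (length(zero)) {
    rlang::abort(paste0("zero cell(s): ", paste(zero, collapse = ", "),
                        "; use haldane = TRUE for the +0.5 correction"),
                 class = "famrisk_zero_cell")
  }
  log_or <- unname(log(cells["a"]) - log(cells["b"]) - log(cells["c"]) + log(cells["d"]))
  se <- sqrt(sum(1 / cells))
  tibble::tibble(
    or = exp(log_or),
    ci_low = exp(log_or - conf_z * se),
    ci_high = exp(log_or + conf_z * se),
    log_or = log_or,
    se_log_or = se)
}

#' Batch Woolf odds ratios over labelled 2x2 tables
#'
#' @param tables Data frame with columns `label`, `a`, `b`, `c`, `d` (or a
#'   CSV path to one).
#' @param ... Passed to [odds_ratio_woolf()].
#' @return Tibble with one row per label and the OR columns.
#' @export
batch_odds_ratios <- function(tables, ...) {
  if (is.character(tables)) tables <- readr::read_csv(tables, show_col_types = FALSE)
  stopifnot(all(c("label", "a", "b", "c", "d") %in% names(tables)))
  tables |>
    dplyr::reframe(odds_ratio_woolf(.data$a, .data$b, .data$c, .data$d, ...),
                   .by = "label")
}

#' Pearson chi-square test on an r x c count table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction) with
#' `df = (r - 1)(c - 1)` and the upper-tail p-value.
#'
#' @param counts Matrix (or data frame) of non-negative counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' pearson_chi_square(rbind(c(125, 136), c(508, 429)))
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) rlang::abort("counts must be non-negative", class = "famrisk_bad_table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    rlang::abort("empty row or column margin", class = "famrisk_empty_margin")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = as.integer(unname(ht$parameter)),
                 p_value = unname(ht$p.value))
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided exact p-value: the sum of hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed one.
#'
#' @inheritParams odds_ratio_woolf
#' @return The p-value.
#' @export
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  cells <- as_2x2(a, b, c, d)
  m <- matrix(cells, 2, 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided independent-samples t-test with pooled variance, for comparing
#' continuous measures (e.g. ages) between arms.
#'
#' @param sample1,sample2 Numeric vectors, each of length >= 2 with positive
#'   variance.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean1`, `mean2`.
#' @export
two_sample_t <- function(sample1, sample2) {
  if (length(sample1) < 2 || length(sample2) < 2) {
    rlang::abort("each sample needs n >= 2", class = "famrisk_bad_sample")
  }
  if (stats::var(sample1) + stats::var(sample2) <= 0) {
    rlang::abort("degenerate (zero) variance in both samples", class = "famrisk_bad_sample")
  }
  ht <- stats::t.test(sample1, sample2, var.equal = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 mean1 = mean(sample1), mean2 = mean(sample2))
}
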