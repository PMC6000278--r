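#' @keywords internal
#' @importFrom rlang .data
#' @importFrom survival strata clogit coxph Surv
"_PACKAGE"

## Covariate dictionary shared by the whole package. Codes follow the
## convention that the first (lowest-risk / reference) category is 0 and the
## remaining categories count upwards.

# ordered level codes per covariate term
famrisk_covariates <- list(
  sex                   = 0:1, # 0 female, 1 male
  age_group             = 0:1, # 0 under 50, 1 at least 50
  smoking               = 0:2, # 0 never, 1 index < 400, 2 index >= 400
  lung_disease_history  = 0:1,
  living_contact        = 0:1,
  occupation_expose     = 0:1,
  relatives_with_cancer = 0:2  # number of affected first-degree relatives; 2 means ">= 2"
)

# dummy (treatment-coded) columns per term, reference level 0 dropped
famrisk_dummies <- list(
  sex                   = "sex",
  age_group             = "age_group",
  smoking               = c("smoking_light", "smoking_heavy"),
  lung_disease_history  = "lung_disease_history",
  living_contact        = "living_contact",
  occupation_expose     = "occupation_expose",
  relatives_with_cancer = c("relatives_1", "relatives_2plus")
)

#' Covariate terms understood by the models
#'
#' All model-fitting functions name covariates by these terms; multi-level
#' terms (smoking, `relatives_with_cancer`) expand to two treatment-coded
#' dummy indicators with level 0 as the reference.
#'
#' @return Character vector of term names.
#' @export
#' @examples
#' covariate_terms()
covariate_terms <- function() names(famrisk_covariates)

#' Terms retained in the published familial risk model
#'
#' The five covariates of the reference forecasting model: sex, smoking
#' category, lung-disease history, occupational exposure and the number of
#' first-degree relatives with cancer.
#'
#' @return Character vector of term names.
#' @export
risk_model_terms <- function() {
  c("sex", "smoking", "lung_disease_history", "occupation_expose",
    "relatives_with_cancer")
}

# map a term + level code to its dummy row (vector over the term's dummies)
dummy_row <- function(term, code) {
  cols <- famrisk_dummies[[term]]
  if (length(cols) == 1L) return(stats::setNames(as.numeric(code), cols))
  out <- stats::setNames(numeric(length(cols)), cols)
  if (code > 0) out[code] <- 1
  out
}

#' Build a treatment-coded design matrix from subject records
#'
#' Expands the requested covariate terms of a subjects table into 0/1 dummy
#' columns (reference level 0 dropped), the coding used by every model in the
#' package.
#'
#' @param data Data frame of subject records with integer-coded covariates.
#' @param terms Character vector of covariate terms (see [covariate_terms()]).
#' @return Numeric matrix with one column per dummy; attribute `"blocks"`
#'   maps each term to its dummy column names.
#' @export
#' @examples
#' cohort <- simulate_matched_cohort(cohort_config(n_pairs = 5, seed = 1))
#' head(build_design(cohort, c("sex", "smoking")))
build_design <- function(data, terms) {
  stopifnot(is.data.frame(data))
  bad <- setdiff(terms, covariate_terms())
  if (length(bad)) {
    rlang::abort(paste0("unknown covariate term(s): ", paste(bad, collapse = ", ")),
                 class = "famrisk_bad_term")
  }
  miss <- setdiff(terms, names(data))
  if (length(miss)) {
    rlang::abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                 class = "famrisk_missing_column")
  }
  blocks <- famrisk_dummies[terms]
  if (!length(terms)) {
    out <- matrix(numeric(0), nrow = nrow(data), ncol = 0)
    attr(out, "blocks") <- stats::setNames(list(), character())
    return(out)
  }
  cols <- lapply(terms, function(tm) {
    x <- data[[tm]]
    dn <- famrisk_dummies[[tm]]
    if (length(dn) == 1L) {
      m <- matrix(as.numeric(x), ncol = 1)
    } else {
      m <- cbind(as.numeric(x == 1), as.numeric(x == 2))
    }
    colnames(m) <- dn
    m
  })
  out <- do.call(cbind, cols)
  attr(out, "blocks") <- blocks
  out
}

# all dummy names for a set of terms, in order
dummy_names <- function(terms) unlist(famrisk_dummies[terms], use.names = FALSE)

expit <- function(x) stats::plogis(x)
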