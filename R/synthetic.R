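## Synthetic spouse-matched cohort generator.
##
## The generator emulates a 1:1 spouse-matched case-control design: a rare
## disease in the population follows a logistic model on coded covariates;
## cases are ascertained conditional on disease and each contributes a
## disease-free spouse as the matched control.

#' Default population covariate prevalences
#'
#' Category probabilities (per covariate, summing to one) loosely matched to
#' the control margins of the motivating study: about 20% of subjects under
#' 50, ~15% with daily living-environment carcinogen contact, and ~22% of
#' families with at least one affected first-degree relative. These are
#' approximations — the study prints only marginal counts.
#'
#' @return Named list of probability vectors, one per [covariate_terms()].
#' @export
default_prevalences <- function() {
  list(
    sex                   = c(0.5, 0.5),
    age_group             = c(0.2, 0.8),
    smoking               = c(0.60, 0.20, 0.20),
    lung_disease_history  = c(0.95, 0.05),
    living_contact        = c(0.85, 0.15),
    occupation_expose     = c(0.85, 0.15),
    relatives_with_cancer = c(0.78, 0.19, 0.03)
  )
}

#' Configure a synthetic matched-cohort simulation
#'
#' @param n_pairs Number of case-control pairs (>= 1).
#' @param true_betas Named numeric vector of log-odds effects on the dummy
#'   scale (names from the dummy columns of [build_design()], e.g.
#'   `smoking_heavy`); unnamed dummies get effect 0. Defaults to the
#'   reference risk-model coefficients.
#' @param alpha_pop Population-model intercept on the log-odds scale.
#' @param covariate_prevalences Named list of category probabilities per
#'   covariate term; see [default_prevalences()].
#' @param spouse_sex_flip_prob Probability that a spouse's sex is the
#'   opposite of the case's; otherwise it is an independent draw from the sex
#'   prevalence. 1 reproduces the spousal design.
#' @param shared_living_contact Should the spouse share the case's
#'   living-environment contact code (spouses share a household)?
#' @param q1 Population disease incidence used as the default projection
#'   prior; must lie in (0, 0.5). The generator's own marginal incidence is
#'   [implied_incidence()].
#' @param seed Integer seed; all randomness in the simulation flows from it.
#' @return A validated `famrisk_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_pairs = 50, seed = 42)
#' implied_incidence(cfg)
cohort_config <- function(n_pairs,
                          true_betas = reference_betas(),
                          alpha_pop = -8.59,
                          covariate_prevalences = default_prevalences(),
                          spouse_sex_flip_prob = 1,
                          shared_living_contact = TRUE,
                          q1 = 49.7e-5,
                          seed = 1L) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || is.na(n_pairs) || n_pairs < 1) {
    rlang::abort("n_pairs must be a single integer >= 1", class = "famrisk_bad_config")
  }
  n_pairs <- as.integer(n_pairs)
  all_dummies <- dummy_names(covariate_terms())
  beta <- stats::setNames(numeric(length(all_dummies)), all_dummies)
  if (length(true_betas)) {
    bad <- setdiff(names(true_betas), all_dummies)
    if (length(bad)) {
      rlang::abort(paste0("unknown dummy name(s) in true_betas: ",
                          paste(bad, collapse = ", ")),
                   class = "famrisk_bad_config")
    }
    beta[names(true_betas)] <- true_betas
  }
  terms <- covariate_terms()
  if (!setequal(names(covariate_prevalences), terms)) {
    rlang::abort("covariate_prevalences must name every covariate term",
                 class = "famrisk_bad_config")
  }
  for (tm in terms) {
    p <- covariate_prevalences[[tm]]
    if (length(p) != length(famrisk_covariates[[tm]]) || any(p < 0) || any(p > 1) ||
        abs(sum(p) - 1) > 1e-8) {
      rlang::abort(paste0("prevalences for '", tm,
                          "' must be probabilities summing to 1 over its levels"),
                   class = "famrisk_bad_config")
    }
  }
  if (spouse_sex_flip_prob < 0 || spouse_sex_flip_prob > 1) {
    rlang::abort("spouse_sex_flip_prob must lie in [0, 1]", class = "famrisk_bad_config")
  }
  if (!(q1 > 0 && q1 < 0.5)) {
    rlang::abort("q1 must lie in (0, 0.5)", class = "famrisk_bad_config")
  }
  cfg <- structure(
    list(n_pairs = n_pairs, true_betas = beta, alpha_pop = alpha_pop,
         covariate_prevalences = covariate_prevalences[terms],
         spouse_sex_flip_prob = spouse_sex_flip_prob,
         shared_living_contact = isTRUE(shared_living_contact),
         q1 = q1, seed = as.integer(seed)),
    class = "famrisk_config")
  lat <- pattern_lattice(cfg)
  if (max(lat$p_disease) > 0.5) {
    rlang::abort(
      sprintf(paste0("implied disease probability reaches %.3f (> 0.5) for some ",
                     "covariate pattern; lower alpha_pop or the effect sizes ",
                     "to keep the rare-disease sampling design meaningful"),
              max(lat$p_disease)),
      class = "famrisk_bad_config")
  }
  cfg
}

# Enumerate the full discrete covariate lattice (one row per joint pattern)
# with its population probability and disease probability under the config.
pattern_lattice <- function(config) {
  terms <- covariate_terms()
  grid <- do.call(expand.grid, c(famrisk_covariates[terms],
                                 KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  names(grid) <- terms
  pr <- rep(1, nrow(grid))
  for (tm in terms) {
    pr <- pr * config$covariate_prevalences[[tm]][grid[[tm]] + 1L]
  }
  X <- build_design(grid, terms)
  logit <- as.numeric(config$alpha_pop + X %*% config$true_betas[colnames(X)])
  tibble::as_tibble(grid) |>
    dplyr::mutate(prob = pr, logit = logit, p_disease = expit(logit))
}

#' Marginal disease incidence implied by a simulation configuration
#'
#' Sums `P(x) * expit(alpha_pop + beta'x)` exactly over the discrete
#' covariate lattice. This is the incidence the generator's own population
#' follows; use it as the prior `q1` when checking the intercept-offset
#' identity on simulated data.
#'
#' @param config A [cohort_config()].
#' @return A probability.
#' @export
implied_incidence <- function(config) {
  stopifnot(inherits(config, "famrisk_config"))
  lat <- pattern_lattice(config)
  sum(lat$prob * lat$p_disease)
}

# draw n subjects' covariates from the prevalences (population model)
draw_covariates <- function(n, prevalences) {
  out <- lapply(covariate_terms(), function(tm) {
    p <- prevalences[[tm]]
    sample(famrisk_covariates[[tm]], n, replace = TRUE, prob = p)
  })
  names(out) <- covariate_terms()
  tibble::as_tibble(out)
}

disease_prob <- function(data, config) {
  X <- build_design(data, covariate_terms())
  expit(as.numeric(config$alpha_pop + X %*% config$true_betas[colnames(X)]))
}

#' Simulate a spouse-matched case-control cohort
#'
#' Cases are drawn exactly from the population distribution of covariate
#' patterns conditional on disease (the covariate lattice is discrete, so the
#' conditional distribution is enumerable); each case's spouse has sex
#' opposite to the case with probability `spouse_sex_flip_prob`, shares the
#' case's living-environment contact when `shared_living_contact` is set,
#' draws all other covariates from the population prevalences, and is
#' accepted as the matched control conditional on being disease-free.
#'
#' @param config A [cohort_config()].
#' @return Tibble of `2 * n_pairs` subject records with columns
#'   `subject_id`, `pair_id`, `arm` (1 case / 0 control), and the integer
#'   covariate codes of [covariate_terms()]; deterministic for a fixed seed.
#' @export
#' @examples
#' cohort <- simulate_matched_cohort(cohort_config(n_pairs = 10, seed = 7))
#' dplyr::count(cohort, arm)
simulate_matched_cohort <- function(config) {
  stopifnot(inherits(config, "famrisk_config"))
  n <- config$n_pairs
  prev <- config$covariate_prevalences
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  lat <- pattern_lattice(config)
  w_case <- lat$prob * lat$p_disease
  idx <- sample.int(nrow(lat), n, replace = TRUE, prob = w_case)
  cases <- lat[idx, covariate_terms()]

  # spouse: sex / living contact tied to the case, rest population draws,
  # retained conditional on being disease-free (rejection; acceptance is
  # ~1 - p_disease, essentially certain at rare-disease incidence)
  spouses <- draw_covariates(n, prev)
  flip <- stats::runif(n) < config$spouse_sex_flip_prob
  spouses$sex[flip] <- 1L - cases$sex[flip]
  if (config$shared_living_contact) spouses$living_contact <- cases$living_contact
  pending <- which(stats::runif(n) < disease_prob(spouses, config))
  while (length(pending)) {
    redo <- draw_covariates(length(pending), prev)
    flip <- stats::runif(length(pending)) < config$spouse_sex_flip_prob
    redo$sex[flip] <- 1L - cases$sex[pending][flip]
    if (config$shared_living_contact) {
      redo$living_contact <- cases$living_contact[pending]
    }
    spouses[pending, ] <- redo
    keep <- stats::runif(length(pending)) >= disease_prob(redo, config)
    pending <- pending[!keep]
  }

  cases$pair_id <- seq_len(n)
  spouses$pair_id <- seq_len(n)
  cases$arm <- 1L
  spouses$arm <- 0L
  out <- dplyr::bind_rows(cases, spouses) |>
    dplyr::arrange(.data$pair_id, dplyr::desc(.data$arm)) |>
    dplyr::mutate(
      subject_id = sprintf("P%05d_%s", .data$pair_id,
                           ifelse(.data$arm == 1L, "case", "ctrl"))) |>
    dplyr::select("subject_id", "pair_id", "arm", dplyr::all_of(covariate_terms()))
  dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric), as.integer))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
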