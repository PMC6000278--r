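## End-to-end orchestration: simulate or load subjects, tabulate balance and
## crude/adjusted ORs, select and fit the risk model, recalibrate, enumerate
## strata, evaluate classification; every artifact is a headered CSV (or
## JSON) with a schema sidecar.

#' Configure a pipeline run
#'
#' Exactly one of `input` (a subjects CSV path) or `simulation` (a
#' [cohort_config()]) must be given.
#'
#' @param input Path to a subjects CSV, or `NULL`.
#' @param simulation A [cohort_config()], or `NULL`.
#' @param prior A [population_prior()].
#' @param p_enter,p_remove Stepwise thresholds.
#' @param mode Stratum probability mode ([stratum_probability()]).
#' @param grid Stratum grid ([enumerate_strata()]).
#' @param rr_threshold High-risk subgroup threshold.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for any simulation randomness; defaults to the
#'   simulation config's own seed when one is given.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `famrisk_run_config` list.
#' @export
run_config <- function(input = NULL, simulation = NULL,
                       prior = reference_prior(),
                       p_enter = 0.05, p_remove = 0.10,
                       mode = c("odds_approx", "expit"),
                       grid = c("observed", "full"),
                       rr_threshold = 10, out_dir = tempfile("famrisk_run_"),
                       seed = NULL, log_level = c("info", "quiet")) {
  if (is.null(input) == is.null(simulation)) {
    rlang::abort("exactly one of input / simulation must be given",
                 class = "famrisk_bad_config")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation, "famrisk_config"))
  if (is.null(seed)) seed <- if (is.null(simulation)) 1L else simulation$seed
  structure(list(input = input, simulation = simulation, prior = prior,
                 p_enter = p_enter, p_remove = p_remove,
                 mode = match.arg(mode), grid = match.arg(grid),
                 rr_threshold = rr_threshold, out_dir = out_dir,
                 seed = as.integer(seed), log_level = match.arg(log_level)),
            class = "famrisk_run_config")
}

write_artifact <- function(df, path) {
  readr::write_csv(df, path)
  schema <- list(columns = as.list(names(df)))
  jsonlite::write_json(schema, paste0(path, ".schema.json"), auto_unbox = TRUE)
  path
}

#' Validate a pipeline CSV against its schema sidecar
#'
#' @param path CSV path written by [run_pipeline()].
#' @return `TRUE` invisibly; errors when the header does not match.
#' @export
validate_output_csv <- function(path) {
  schema <- jsonlite::read_json(paste0(path, ".schema.json"), simplifyVector = TRUE)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(hdr, as.character(schema$columns))) {
    rlang::abort(paste0("schema mismatch for ", path), class = "famrisk_bad_schema")
  }
  invisible(TRUE)
}

# labelled 2x2 family-history tables from subject records (exposed = the
# family-history factor level, unexposed = no affected relatives)
family_history_tables <- function(subjects, stratum = "all") {
  n_rel <- function(arm, lev) {
    if (identical(lev, "any")) sum(subjects$arm == arm & subjects$relatives_with_cancer >= 1)
    else sum(subjects$arm == arm & subjects$relatives_with_cancer == lev)
  }
  purrr::map(list("any", 1L, 2L), function(lev) {
    tibble::tibble(
      stratum = stratum,
      label = paste0("relatives_", if (identical(lev, "any")) "any" else
        if (lev == 2L) "2plus" else "1"),
      a = n_rel(1L, lev), b = n_rel(1L, 0L),
      c = n_rel(0L, lev), d = n_rel(0L, 0L))
  }) |> dplyr::bind_rows()
}

# stratify each pair by the CASE's age group
split_pairs_by_case_age <- function(subjects) {
  case_age <- subjects |>
    dplyr::filter(.data$arm == 1) |>
    dplyr::select("pair_id", case_age = "age_group")
  dplyr::left_join(subjects, case_age, by = "pair_id")
}

#' Run the whole analysis pipeline
#'
#' Sequences simulate/load -> balance tables -> crude and adjusted ORs ->
#' forward stepwise risk model -> intercept recalibration -> stratum
#' enumeration -> classification, writing `table1_balance.csv`,
#' `table23_or.csv`, `table4_model.csv`, `stepwise_trace.json`,
#' `table5_strata.csv`, `table6_classification.csv`,
#' `table78_highrisk.csv`, `run.json` and `run.log` into the output
#' directory. Idempotent for a fixed seed. A stage failure aborts with the
#' stage name; artifacts already written are preserved.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the output directory, per-artifact paths
#'   and the fitted objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "famrisk_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    if (config$log_level == "info") message(msg)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      say("stage %s: FAILED (%s)", name, conditionMessage(e))
      rlang::abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
                   class = "famrisk_stage_error", parent = e)
    })
  }
  paths <- list()

  subjects <- stage("input", {
    if (!is.null(config$input)) read_subjects(config$input)
    else {
      sim <- config$simulation
      sim$seed <- config$seed
      simulate_matched_cohort(sim)
    }
  })
  say("subjects: %d records, %d pairs", nrow(subjects), length(unique(subjects$pair_id)))

  paths$balance <- stage("balance", {
    rows <- purrr::map(c("age_group", "living_contact", "occupation_expose"), function(tm) {
      tab <- table(subjects[[tm]], subjects$arm)
      chi <- pearson_chi_square(tab)
      tibble::tibble(characteristic = tm, statistic = chi$statistic,
                     df = chi$df, p_value = chi$p_value)
    }) |> dplyr::bind_rows()
    write_artifact(rows, file.path(config$out_dir, "table1_balance.csv"))
  })

  paths$or <- stage("crude_adjusted_or", {
    strat <- split_pairs_by_case_age(subjects)
    tabs <- dplyr::bind_rows(
      family_history_tables(subjects, "all"),
      family_history_tables(dplyr::filter(strat, .data$case_age == 0), "under50"),
      family_history_tables(dplyr::filter(strat, .data$case_age == 1), "over50"))
    safe_or <- function(a, b, c, d) {
      tryCatch(odds_ratio_woolf(a, b, c, d),
               error = function(e) tibble::tibble(or = NA_real_, ci_low = NA_real_,
                                                  ci_high = NA_real_, log_or = NA_real_,
                                                  se_log_or = NA_real_))
    }
    crude <- dplyr::bind_cols(
      tabs, purrr::pmap_dfr(tabs[c("a", "b", "c", "d")], safe_or))
    adj <- tryCatch({
      fit <- suppressWarnings(fit_conditional_logistic(
        subjects, c("relatives_with_cancer", "sex", "lung_disease_history",
                    "smoking", "living_contact", "occupation_expose")))
      adjusted_or_table(fit) |> dplyr::mutate(kind = "adjusted", .before = 1)
    }, error = function(e) {
      say("adjusted ORs unavailable: %s", conditionMessage(e))
      NULL
    })
    p <- write_artifact(crude, file.path(config$out_dir, "table23_or.csv"))
    if (!is.null(adj)) write_artifact(adj, file.path(config$out_dir, "table23_adjusted_or.csv"))
    p
  })

  sel <- stage("stepwise", {
    forward_stepwise(subjects, covariate_terms(),
                     p_enter = config$p_enter, p_remove = config$p_remove)
  })
  say("stepwise selected: %s", paste(sel$included, collapse = ", "))
  paths$model <- stage("model_table", {
    jsonlite::write_json(sel$trace, file.path(config$out_dir, "stepwise_trace.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    write_artifact(tidy(sel$model), file.path(config$out_dir, "table4_model.csv"))
  })

  corrected <- stage("correction", {
    fit <- if (setequal(sel$included, risk_model_terms())) sel$model
           else fit_logistic_ml(subjects, risk_model_terms())
    correct_model(fit, config$prior)
  })
  say("intercept: a' = %.4f -> a = %.4f", corrected$model$intercept, corrected$a)

  strata <- stage("strata", {
    enumerate_strata(subjects, corrected, grid = config$grid, mode = config$mode)
  })
  paths$strata <- write_artifact(tibble::as_tibble(strata),
                                 file.path(config$out_dir, "table5_strata.csv"))

  paths$classification <- stage("classification", {
    probs <- predict_probability(corrected$model, subjects)
    cls <- classification_table(subjects$arm, probs)
    write_artifact(
      dplyr::bind_cols(tidy(cls) |>
                         tidyr::pivot_wider(names_from = "predicted",
                                            values_from = "count",
                                            names_prefix = "predicted_"),
                       glance(cls)[rep(1, 2), c("overall_pct", "unclassified")]),
      file.path(config$out_dir, "table6_classification.csv"))
  })

  paths$highrisk <- stage("high_risk", {
    cls_hi <- withCallingHandlers(
      high_risk_subgroup_eval(subjects, corrected, strata = strata,
                              rr_threshold = config$rr_threshold),
      famrisk_empty_subgroup = function(w) {
        say("high-risk subgroup empty")
        rlang::cnd_muffle(w)
      })
    write_artifact(glance(cls_hi), file.path(config$out_dir, "table78_highrisk.csv"))
  })

  stage("run_record", {
    jsonlite::write_json(
      list(seed = config$seed,
           package_version = as.character(utils::packageVersion("famrisk")),
           r_version = as.character(getRversion()),
           p_enter = config$p_enter, p_remove = config$p_remove,
           mode = config$mode, grid = config$grid,
           rr_threshold = config$rr_threshold,
           prior = unclass(config$prior),
           input = if (is.null(config$input)) NULL else normalizePath(config$input),
           simulation = if (is.null(config$simulation)) NULL else {
             s <- unclass(config$simulation)
             s$true_betas <- as.list(s$true_betas)
             s
           },
           selected_terms = sel$included),
      file.path(config$out_dir, "run.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  })
  say("run complete: %s", config$out_dir)
  invisible(list(out_dir = config$out_dir, paths = paths, subjects = subjects,
                 stepwise = sel, corrected = corrected, strata = strata))
}

#' Write bundled or synthetic fixtures to disk
#'
#' `"reference_tables"` copies the bundled printed-table CSVs
#' ([reference_counts()], coefficients and prior); `"small_synthetic"`
#' writes a seeded 200-pair synthetic subjects CSV.
#'
#' @param name `"reference_tables"` or `"small_synthetic"`.
#' @param dir Output directory.
#' @param seed Seed for the synthetic fixture.
#' @return Character vector of the files written.
#' @export
make_fixture <- function(name, dir = tempfile("famrisk_fix_"), seed = 7L) {
  opts <- c("reference_tables", "small_synthetic")
  if (!name %in% opts) {
    rlang::abort(paste0("unknown fixture '", name, "'; options: ",
                        paste(opts, collapse = ", ")),
                 class = "famrisk_bad_fixture")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "reference_tables") {
    files <- c("reference_balance_counts.csv", "reference_or_tables.csv",
               "reference_coefficients.csv", "reference_prior.csv",
               "reference_classification_overall.csv",
               "reference_highrisk_strata.csv")
    out <- file.path(dir, files)
    file.copy(vapply(files, ref_path, character(1)), out, overwrite = TRUE)
    out
  } else {
    cohort <- simulate_matched_cohort(cohort_config(n_pairs = 200, seed = seed))
    out <- file.path(dir, "small_synthetic_subjects.csv")
    write_subjects(cohort, out)
    out
  }
}
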