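## Subject CSV input/output with strict code validation.

subject_columns <- function() {
  c("subject_id", "pair_id", "arm", covariate_terms())
}

#' Validate a subjects table
#'
#' Checks column presence, code ranges (every categorical code within its
#' declared range, arm in {0, 1}) and subject-id uniqueness. Errors name the
#' offending field and row.
#'
#' @param subjects Data frame of subject records.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_subjects <- function(subjects) {
  stopifnot(is.data.frame(subjects))
  miss <- setdiff(subject_columns(), names(subjects))
  if (length(miss)) {
    rlang::abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                 class = "famrisk_missing_column")
  }
  subjects <- tibble::as_tibble(subjects)
  dup <- subjects$subject_id[duplicated(subjects$subject_id)]
  if (length(dup)) {
    rlang::abort(paste0("duplicated subject_id: ", paste(unique(dup), collapse = ", ")),
                 class = "famrisk_duplicate_id")
  }
  ranges <- c(list(arm = 0:1), famrisk_covariates)
  for (field in names(ranges)) {
    x <- subjects[[field]]
    bad <- which(!is.na(x) & !(x %in% ranges[[field]]))
    if (length(bad)) {
      rlang::abort(sprintf("out-of-range code for '%s' at row %s (value %s)",
                           field, bad[1], x[bad[1]]),
                   class = "famrisk_bad_code")
    }
  }
  subjects
}

#' Audit case-control pairing
#'
#' Scans pair ids for pairs that do not link exactly one case with exactly
#' one control and warns with the offending ids.
#'
#' @param subjects Data frame of subject records.
#' @return Tibble of unpaired or malformed pairs (`pair_id`, `n_case`,
#'   `n_control`); zero rows when the pairing is clean.
#' @export
audit_pairing <- function(subjects) {
  bad <- subjects |>
    dplyr::summarise(n_case = sum(.data$arm == 1), n_control = sum(.data$arm == 0),
                     .by = "pair_id") |>
    dplyr::filter(.data$n_case != 1L | .data$n_control != 1L)
  if (nrow(bad)) {
    rlang::warn(paste0("unpaired or malformed pair_id(s): ",
                       paste(bad$pair_id, collapse = ", ")),
                class = "famrisk_unpaired")
  }
  bad
}

#' Read subject records from CSV
#'
#' Reads and validates a subjects CSV (integer covariate codes, header naming
#' all fields) and audits the case-control pairing with a warning for
#' unpaired ids.
#'
#' @param path CSV path.
#' @return Tibble of validated subject records.
#' @export
read_subjects <- function(path) {
  subjects <- readr::read_csv(path, show_col_types = FALSE)
  int_cols <- setdiff(subject_columns(), "subject_id")
  for (cl in intersect(int_cols, names(subjects))) {
    subjects[[cl]] <- as.integer(subjects[[cl]])
  }
  if ("subject_id" %in% names(subjects)) {
    subjects$subject_id <- as.character(subjects$subject_id)
  }
  subjects <- validate_subjects(subjects)
  audit_pairing(subjects)
  subjects
}

#' Write subject records to CSV
#'
#' @param subjects Data frame of subject records (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  subjects <- validate_subjects(subjects)
  readr::write_csv(subjects[subject_columns()], path)
  invisible(path)
}
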