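#' Write a cohort to delimited text files
#'
#' Writes `results.csv` (one laboratory record per row, ISO-8601 dates) and
#' `covariates.csv` (one patient per row) into `dir`, and `truth.json` when a
#' truth record is supplied.
#'
#' @param cohort Tibble of laboratory records (`patient_id`, `date`, `value`,
#'   `unit`, optionally `record_id`).
#' @param covariates Tibble of per-patient covariates, or `NULL`.
#' @param dir Output directory; created if absent.
#' @param truth Optional `truth_record` from [generate_cohort()]; stored as
#'   JSON without its config environment.
#'
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, covariates = NULL, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort, file.path(dir, "results.csv"))
  if (!is.null(covariates)) {
    readr::write_csv(covariates, file.path(dir, "covariates.csv"))
  }
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(patients = truth$patients, record_flags = truth$record_flags),
      file.path(dir, "truth.json"),
      dataframe = "columns", digits = NA
    )
  }
  invisible(dir)
}

#' Read a cohort from delimited text files
#'
#' @param dir Directory holding `results.csv` and optionally
#'   `covariates.csv`, as written by [write_cohort()].
#'
#' @return A list with `cohort` and `covariates` (the latter `NULL` when no
#'   covariate file is present).
#' @export
read_cohort <- function(dir) {
  res_path <- file.path(dir, "results.csv")
  if (!file.exists(res_path)) {
    stop("read_cohort: no results.csv in ", dir, call. = FALSE)
  }
  cohort <- readr::read_csv(res_path, show_col_types = FALSE)
  cohort$date <- as.Date(cohort$date)
  cov_path <- file.path(dir, "covariates.csv")
  covariates <- if (file.exists(cov_path)) {
    readr::read_csv(cov_path, show_col_types = FALSE)
  }
  list(cohort = cohort, covariates = covariates)
}
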