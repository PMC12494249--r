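#' Configure the cleaning cascade
#'
#' Default thresholds follow the standard cleaning of routinely collected
#' HbA1c data: keep only mmol/mol records; drop values strictly below
#' 20.1 mmol/mol (mostly percentages mis-recorded as mmol/mol) or strictly
#' above 195.1 mmol/mol (implausible); keep one record per patient-day;
#' exclude patients with one identical value on four or more distinct dates
#' (likely duplicated results); require at least four remaining measurements
#' per patient; recode BMI outside (14, 70) to missing. The boundary values
#' 20.1 and 195.1 themselves are kept (strict inequalities).
#'
#' @param unit_kept Unit tag to keep (`"mmol/mol"`).
#' @param low_cut,high_cut Exclusion bounds, mmol/mol; strict inequalities.
#' @param min_measurements Minimum records per patient after all other rules.
#' @param identical_min_run Number of distinct dates with one identical value
#'   (after rounding to 0.1 mmol/mol) that triggers patient exclusion.
#' @param bmi_low,bmi_high Plausible BMI bounds; values strictly outside are
#'   recoded missing.
#'
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(unit_kept = "mmol/mol", low_cut = 20.1,
                            high_cut = 195.1, min_measurements = 4L,
                            identical_min_run = 4L, bmi_low = 14,
                            bmi_high = 70) {
  if (low_cut >= high_cut) {
    stop("cleaning_config: `low_cut` must be below `high_cut`", call. = FALSE)
  }
  if (min_measurements < 2) {
    stop("cleaning_config: `min_measurements` must be >= 2", call. = FALSE)
  }
  if (identical_min_run < 2) {
    stop("cleaning_config: `identical_min_run` must be >= 2", call. = FALSE)
  }
  structure(
    list(unit_kept = unit_kept, low_cut = low_cut, high_cut = high_cut,
         min_measurements = as.integer(min_measurements),
         identical_min_run = as.integer(identical_min_run),
         bmi_low = bmi_low, bmi_high = bmi_high),
    class = "cleaning_config"
  )
}

known_units <- c("mmol/mol", "percent")

#' Keep records in the retained unit
#'
#' @param cohort Lab-record tibble with a `unit` column.
#' @param config A [cleaning_config()].
#' @return List with the filtered `cohort` and `removed`, the number of
#'   records dropped.
#' @export
filter_unit <- function(cohort, config = cleaning_config()) {
  bad <- !(cohort$unit %in% known_units)
  if (any(bad)) {
    stop("filter_unit: unknown unit tag '", cohort$unit[which(bad)[1]],
         "' at row ", which(bad)[1], call. = FALSE)
  }
  keep <- cohort$unit == config$unit_kept
  list(cohort = cohort[keep, , drop = FALSE], removed = sum(!keep))
}

#' Drop implausible values outside the plausible HbA1c range
#'
#' Values strictly below `low_cut` or strictly above `high_cut` are removed;
#' the bounds themselves survive.
#'
#' @inheritParams filter_unit
#' @return List with `cohort`, `removed_low` and `removed_high`.
#' @export
filter_range <- function(cohort, config = cleaning_config()) {
  low <- cohort$value < config$low_cut
  high <- cohort$value > config$high_cut
  list(cohort = cohort[!(low | high), , drop = FALSE],
       removed_low = sum(low), removed_high = sum(high))
}

#' Keep the first result per patient-day
#'
#' Within each (patient, date) group only the record occurring first in
#' input order is retained; later records on the same day are treated as
#' duplications or errors.
#'
#' @inheritParams filter_unit
#' @return List with `cohort` and `removed`.
#' @export
dedupe_same_day <- function(cohort) {
  dup <- duplicated(cohort[, c("patient_id", "date")])
  list(cohort = cohort[!dup, , drop = FALSE], removed = sum(dup))
}

#' Exclude patients with runs of identical results
#'
#' A patient with the same value (after rounding to the 0.1 mmol/mol
#' reporting resolution) on at least `identical_min_run` distinct dates is
#' removed entirely: such runs are considered duplicated results rather than
#' genuine stability. Same-day deduplication must already have been applied.
#'
#' @inheritParams filter_unit
#' @return List with `cohort`, `removed_patients` and `removed_records`.
#' @export
drop_identical_runs <- function(cohort, config = cleaning_config()) {
  if (nrow(cohort) == 0L) {
    return(list(cohort = cohort, removed_patients = 0L, removed_records = 0L))
  }
  key <- paste(cohort$patient_id, round(cohort$value, 1), sep = "\r")
  run_len <- stats::ave(seq_along(key), key, FUN = length)
  flagged <- unique(cohort$patient_id[run_len >= config$identical_min_run])
  keep <- !(cohort$patient_id %in% flagged)
  list(cohort = cohort[keep, , drop = FALSE],
       removed_patients = length(flagged), removed_records = sum(!keep))
}

#' Require a minimum number of measurements per patient
#'
#' @inheritParams filter_unit
#' @return List with `cohort`, `removed_patients` and `removed_records`.
#' @export
require_min_measurements <- function(cohort, config = cleaning_config()) {
  if (nrow(cohort) == 0L) {
    return(list(cohort = cohort, removed_patients = 0L, removed_records = 0L))
  }
  n_i <- stats::ave(rep(1L, nrow(cohort)), cohort$patient_id, FUN = length)
  keep <- n_i >= config$min_measurements
  list(cohort = cohort[keep, , drop = FALSE],
       removed_patients = length(unique(cohort$patient_id[!keep])),
       removed_records = sum(!keep))
}

#' Recode implausible BMI values to missing
#'
#' BMI strictly below `bmi_low` or strictly above `bmi_high` becomes `NA`;
#' the bounds themselves are kept.
#'
#' @param covariates Per-patient covariate tibble with a `bmi` column.
#' @param config A [cleaning_config()].
#' @return List with `covariates` and `recoded`, the number of values set
#'   to missing.
#' @export
recode_bmi <- function(covariates, config = cleaning_config()) {
  if (is.null(covariates) || !("bmi" %in% names(covariates))) {
    return(list(covariates = covariates, recoded = 0L))
  }
  bad <- !is.na(covariates$bmi) &
    (covariates$bmi < config$bmi_low | covariates$bmi > config$bmi_high)
  covariates$bmi[bad] <- NA_real_
  list(covariates = covariates, recoded = sum(bad))
}

#' Run the full cleaning cascade
#'
#' Applies the rules in a fixed order — unit filter, plausibility range,
#' same-day deduplication, identical-run exclusion, minimum-measurement
#' requirement — so that the patient-level exclusions act on plausible,
#' deduplicated records, and recodes implausible BMI in the covariates.
#' Patients whose record count reaches zero during a record-level stage are
#' attributed to that stage in the report.
#'
#' @param cohort Lab-record tibble (`patient_id`, `date`, `value`, `unit`).
#' @param covariates Optional per-patient covariate tibble.
#' @param config A [cleaning_config()].
#'
#' @return A list with the cleaned `cohort`, the recoded `covariates`, and a
#'   `report` of class `cleaning_report` whose record- and patient-level
#'   counts reconcile exactly with the input sizes.
#' @export
clean_cohort <- function(cohort, covariates = NULL,
                         config = cleaning_config()) {
  records_in <- nrow(cohort)
  patients_in <- length(unique(cohort$patient_id))
  pats <- function(x) unique(x$patient_id)

  s1 <- filter_unit(cohort, config)
  p_after1 <- pats(s1$cohort)
  s2 <- filter_range(s1$cohort, config)
  p_after2 <- pats(s2$cohort)
  s3 <- dedupe_same_day(s2$cohort)
  s4 <- drop_identical_runs(s3$cohort, config)
  s5 <- require_min_measurements(s4$cohort, config)
  bmi <- recode_bmi(covariates, config)

  report <- structure(
    list(
      records_in = records_in,
      patients_in = patients_in,
      records_removed = c(
        unit = s1$removed,
        low = s2$removed_low,
        high = s2$removed_high,
        same_day_duplicate = s3$removed,
        identical_results = s4$removed_records,
        too_few_measurements = s5$removed_records
      ),
      patients_removed = c(
        unit = patients_in - length(p_after1),
        range = length(p_after1) - length(p_after2),
        same_day_duplicate = 0L,
        identical_results = s4$removed_patients,
        too_few_measurements = s5$removed_patients
      ),
      bmi_recoded_missing = bmi$recoded,
      records_out = nrow(s5$cohort),
      patients_out = length(pats(s5$cohort))
    ),
    class = "cleaning_report"
  )
  list(cohort = s5$cohort, covariates = bmi$covariates, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat(sprintf("  input : %d records / %d patients\n", x$records_in, x$patients_in))
  for (nm in names(x$records_removed)) {
    cat(sprintf("  - %-22s %6d records\n", nm, x$records_removed[[nm]]))
  }
  for (nm in names(x$patients_removed)) {
    if (x$patients_removed[[nm]] > 0) {
      cat(sprintf("  - %-22s %6d patients\n", nm, x$patients_removed[[nm]]))
    }
  }
  if (x$bmi_recoded_missing > 0) {
    cat(sprintf("  - BMI recoded missing    %6d values\n", x$bmi_recoded_missing))
  }
  cat(sprintf("  output: %d records / %d patients\n", x$records_out, x$patients_out))
  invisible(x)
}
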