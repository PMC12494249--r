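#' Decade age bands used for subgroup reporting
#' @param age Age in years (vectorised).
#' @return Character band labels `"<=10"`, `"11-20"`, ..., `">100"`.
#' @export
age_band <- function(age) {
  breaks <- c(-Inf, seq(10, 100, by = 10), Inf)
  labels <- c("<=10", paste(seq(11, 91, by = 10), seq(20, 100, by = 10),
                            sep = "-"), ">100")
  as.character(cut(age, breaks = breaks, labels = labels, right = TRUE))
}

#' Standard BMI bands used for subgroup reporting
#' @param bmi BMI in kg/m^2 (vectorised); `NA` maps to `"Missing"`.
#' @return Character band labels.
#' @export
bmi_band <- function(bmi) {
  out <- as.character(cut(bmi, breaks = c(-Inf, 18.5, 25, 30, 35, Inf),
                          labels = c("<18.5", "18.5 to <25", "25 to <30",
                                     "30 to <35", ">35"),
                          right = FALSE))
  out[is.na(bmi)] <- "Missing"
  out
}

#' Per-patient measurement features for subgroup analysis
#'
#' Computes, for each patient, the mean and median HbA1c, the number of
#' measurements, the median gap in days between consecutive measurements,
#' and the calendar year of the first measurement; joins the covariate table
#' when given and adds derived `age_band` and `bmi_band` columns.
#'
#' @param cohort Cleaned lab-record tibble.
#' @param covariates Optional per-patient covariate tibble.
#' @return A tibble with one row per patient.
#' @export
derive_features <- function(cohort, covariates = NULL) {
  feats <- cohort |>
    dplyr::arrange(.data$patient_id, .data$date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      mean_hba1c = mean(.data$value),
      median_hba1c = stats::median(.data$value),
      n_measurements = dplyr::n(),
      median_gap_days = if (dplyr::n() > 1L) {
        stats::median(as.numeric(diff(.data$date)))
      } else NA_real_,
      first_year = as.integer(format(min(.data$date), "%Y")),
      .groups = "drop"
    )
  if (!is.null(covariates)) {
    feats <- dplyr::left_join(feats, covariates, by = "patient_id")
    if ("age" %in% names(feats)) feats$age_band <- age_band(feats$age)
    if ("bmi" %in% names(feats)) feats$bmi_band <- bmi_band(feats$bmi)
  }
  feats
}

#' Specify a subgroup (stratification) analysis
#'
#' @param variable Name of a covariate or derived feature (e.g. `"sex"`,
#'   `"diabetic_status"`, `"age_band"`, `"mean_hba1c"`,
#'   `"median_gap_days"`, `"n_measurements"`, `"first_year"`).
#' @param breaks Optional strictly increasing numeric cut points for a
#'   numeric variable; ignored for categorical variables.
#' @param min_group_size Strata with fewer patients are suppressed (no
#'   estimate is reported for them); default 100.
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(variable, breaks = NULL, min_group_size = 100L) {
  if (!is.character(variable) || length(variable) != 1L) {
    stop("subgroup_spec: `variable` must be a single name", call. = FALSE)
  }
  if (!is.null(breaks)) {
    if (is.unsorted(breaks, strictly = TRUE)) {
      stop("subgroup_spec: `breaks` must be strictly increasing", call. = FALSE)
    }
  }
  if (min_group_size < 2) {
    stop("subgroup_spec: `min_group_size` must be >= 2", call. = FALSE)
  }
  structure(list(variable = variable, breaks = breaks,
                 min_group_size = as.integer(min_group_size)),
            class = "subgroup_spec")
}

# Assign each patient a stratum label for one spec; returns character vector
# aligned with `feats` rows, NA -> "Missing".
assign_strata <- function(feats, spec) {
  if (!(spec$variable %in% names(feats))) {
    stop("subgroup: unknown variable '", spec$variable, "'", call. = FALSE)
  }
  v <- feats[[spec$variable]]
  if (is.numeric(v) && !is.null(spec$breaks)) {
    lab <- as.character(cut(v, breaks = c(-Inf, spec$breaks, Inf), right = FALSE))
  } else {
    lab <- as.character(v)
  }
  lab[is.na(lab)] <- "Missing"
  lab
}

# CV estimate for one patient subset; returns a one-row tibble.
estimate_cell <- function(records, n_patients, engine, level, suppressed) {
  if (suppressed || n_patients == 0L) {
    return(tibble::tibble(
      n_patients = n_patients, n_records = nrow(records),
      mean_hba1c = if (nrow(records)) mean(records$value) else NA_real_,
      cv = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      suppressed = TRUE))
  }
  fit_fun <- if (engine == "reml") fit_components_reml else fit_components_moments
  est <- cv_from_components(fit_fun(records), level)
  tibble::tibble(n_patients = n_patients, n_records = nrow(records),
                 mean_hba1c = mean(records$value), cv = est$cv,
                 ci_low = est$ci_low, ci_high = est$ci_high,
                 suppressed = FALSE)
}

#' Stratified within-individual CV
#'
#' Repeats the variance-components CV estimation on subsets of the cohort
#' defined by one covariate or derived feature. Each stratum keeps all the
#' records of its patients. Strata below the participant floor are reported
#' with counts only and a `suppressed` flag; a `Missing` category is
#' reported separately.
#'
#' When `variable` names a record-level column of `cohort` (a covariate that
#' changes over time, such as diabetic status recorded per result), a
#' patient contributes to a stratum only the segment of at least
#' `min_segment` records carrying that value; patients with no qualifying
#' segment are excluded from that analysis.
#'
#' @param cohort Cleaned lab-record tibble.
#' @param spec A [subgroup_spec()].
#' @param covariates Optional per-patient covariate tibble.
#' @param engine `"reml"` or `"moments"`.
#' @param level Confidence level.
#' @param min_segment Minimum records per patient-stratum segment in
#'   record-level mode.
#' @return A tibble with one row per stratum: label, counts, mean HbA1c,
#'   CV with confidence interval, and the suppression flag.
#' @export
stratified_cv <- function(cohort, spec, covariates = NULL,
                          engine = c("reml", "moments"), level = 0.95,
                          min_segment = 4L) {
  engine <- match.arg(engine)
  record_level <- spec$variable %in% setdiff(
    names(cohort), c("record_id", "patient_id", "date", "value", "unit"))

  if (record_level) {
    lab <- as.character(cohort[[spec$variable]])
    lab[is.na(lab)] <- "Missing"
    seg_n <- stats::ave(rep(1L, nrow(cohort)),
                        paste(cohort$patient_id, lab, sep = "\r"),
                        FUN = length)
    keep <- seg_n >= min_segment
    sub <- cohort[keep, , drop = FALSE]
    lab <- lab[keep]
    levels_ <- sort(unique(lab))
    out <- lapply(levels_, function(lv) {
      rec <- sub[lab == lv, , drop = FALSE]
      np <- length(unique(rec$patient_id))
      cbind(tibble::tibble(stratum = lv),
            estimate_cell(rec, np, engine, level,
                          suppressed = np < spec$min_group_size))
    })
    return(dplyr::bind_rows(out))
  }

  feats <- derive_features(cohort, covariates)
  lab <- assign_strata(feats, spec)
  levels_ <- sort(unique(lab))
  out <- lapply(levels_, function(lv) {
    ids <- feats$patient_id[lab == lv]
    rec <- cohort[cohort$patient_id %in% ids, , drop = FALSE]
    cbind(tibble::tibble(stratum = lv),
          estimate_cell(rec, length(ids), engine, level,
                        suppressed = length(ids) < spec$min_group_size))
  })
  dplyr::bind_rows(out)
}

#' Cross-classified within-individual CV
#'
#' Estimates the CV in every cell of the Cartesian product of up to four
#' stratification variables (for example sex x ethnicity x age band x
#' diabetic status), the construction behind multi-way subgroup heat maps.
#' Patients with a missing value in any of the variables are excluded from
#' the grid (their count is returned as the `n_excluded_missing` attribute);
#' cells below the participant floor (the largest `min_group_size` of the
#' specs) are suppressed.
#'
#' @param cohort Cleaned lab-record tibble.
#' @param specs List of up to four [subgroup_spec()] objects.
#' @param covariates Optional per-patient covariate tibble.
#' @param engine `"reml"` or `"moments"`.
#' @param level Confidence level.
#' @return A tibble with one row per cell: one label column per variable,
#'   counts, mean HbA1c, CV with interval, suppression flag. Cells with no
#'   patients are retained with zero counts.
#' @export
cross_classified_cv <- function(cohort, specs, covariates = NULL,
                                engine = c("reml", "moments"), level = 0.95) {
  engine <- match.arg(engine)
  if (!length(specs) || length(specs) > 4L) {
    stop("cross_classified_cv: between 1 and 4 specs are supported",
         call. = FALSE)
  }
  feats <- derive_features(cohort, covariates)
  labs <- lapply(specs, function(sp) assign_strata(feats, sp))
  vars <- vapply(specs, `[[`, character(1), "variable")
  names(labs) <- vars
  floor_n <- max(vapply(specs, `[[`, integer(1), "min_group_size"))

  missing_any <- Reduce(`|`, lapply(labs, function(l) l == "Missing"))
  n_excluded <- sum(missing_any)
  keep <- !missing_any
  if (!any(keep)) {
    warning("cross_classified_cv: no patients without missing values; empty grid")
    out <- tibble::tibble()
    attr(out, "n_excluded_missing") <- n_excluded
    return(out)
  }

  lab_df <- tibble::as_tibble(labs)[keep, , drop = FALSE]
  ids <- feats$patient_id[keep]
  grid <- expand.grid(lapply(lab_df, function(l) sort(unique(l))),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_key <- do.call(paste, c(lab_df, sep = "\r"))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    key <- paste(unlist(grid[i, , drop = TRUE]), collapse = "\r")
    cell_ids <- ids[cell_key == key]
    rec <- cohort[cohort$patient_id %in% cell_ids, , drop = FALSE]
    cbind(tibble::as_tibble(grid[i, , drop = FALSE]),
          estimate_cell(rec, length(cell_ids), engine, level,
                        suppressed = length(cell_ids) < floor_n))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "n_excluded_missing") <- n_excluded
  out
}
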