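# Truncated-normal draws by inverse CDF; sd may be 0 (degenerate at mean).
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (length(mean) == 1L) mean <- rep(mean, n)
  if (length(sd) == 1L) sd <- rep(sd, n)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    plo <- stats::pnorm(lo, mean[pos], sd[pos])
    phi <- stats::pnorm(hi, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), plo, phi)
    out[pos] <- stats::qnorm(u, mean[pos], sd[pos])
  }
  out
}

draw_categorical <- function(n, probs) {
  if (n == 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic longitudinal HbA1c cohort
#'
#' Draws a seeded cohort with the structure the downstream pipeline assumes:
#' patient-level true mean HbA1c per stratum (truncated normal on
#' 20.1-195.1 mmol/mol), repeated results with constant within-patient CV
#' (normal noise with SD proportional to the true mean, truncated at zero),
#' visit counts from a discretised log-normal, and visit dates with uniform
#' gaps. On top of the clean draws the generator injects, at the configured
#' rates, the error modes routinely seen in EHR laboratory data: percentage
#' values mis-recorded under the mmol/mol unit tag, implausibly high values,
#' same-day duplicate records, and patients whose results are all one
#' identical value.
#'
#' @param config A [sim_config()].
#'
#' @return A list with components:
#' \describe{
#'   \item{cohort}{Tibble of laboratory records: `record_id`, `patient_id`,
#'     `date`, `value`, `unit`.}
#'   \item{covariates}{One row per patient: demographics, lifestyle,
#'     diabetic status and comorbidity flags.}
#'   \item{truth}{A `truth_record`: per-patient latent true means and strata,
#'     plus per-record injected-error flags, for recovery testing.}
#' }
#' @seealso [truth_summary()], [clean_cohort()]
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("generate_cohort: `config` must be a sim_config object", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_patients
  strata <- config$strata
  w <- vapply(strata, `[[`, numeric(1), "weight")

  stratum_idx <- sample.int(length(strata), n, replace = TRUE, prob = w)
  patient_id <- sprintf("P%06d", seq_len(n))

  # latent true means, truncated to the plausible mmol/mol range
  centers <- vapply(strata, `[[`, numeric(1), "true_mean_center")[stratum_idx]
  sds <- vapply(strata, `[[`, numeric(1), "true_mean_sd")[stratum_idx]
  true_mean <- rnorm_trunc(n, centers, sds, lo = 20.1, hi = 195.1)
  within_cv <- vapply(strata, `[[`, numeric(1), "within_cv")[stratum_idx]

  # visit counts: discretised log-normal (median 11, IQR 7-18 by default)
  vl <- config$visit_count_law
  n_visits <- pmax(as.integer(vl$min),
                   as.integer(round(stats::rlnorm(n, vl$meanlog, vl$sdlog))))

  # covariates, drawn stratum by stratum in stratum order
  covariates <- tibble::tibble(
    patient_id = patient_id,
    diabetic_status = vapply(strata, `[[`, character(1), "label")[stratum_idx],
    age = NA_integer_, sex = NA_character_, ethnicity = NA_character_,
    deprivation = NA_character_, bmi = NA_real_, smoking = NA_character_,
    alcohol = NA_character_, on_glucose_lowering_med = NA,
    hypertension = NA, ihd = NA, cancer = NA
  )
  for (s in seq_along(strata)) {
    idx <- which(stratum_idx == s)
    if (!length(idx)) next
    cl <- strata[[s]]$covariate_laws
    m <- length(idx)
    covariates$age[idx] <- as.integer(round(
      rnorm_trunc(m, cl$age$mean, cl$age$sd, cl$age$min, cl$age$max)))
    covariates$sex[idx] <- draw_categorical(m, cl$sex)
    covariates$ethnicity[idx] <- draw_categorical(m, cl$ethnicity)
    covariates$deprivation[idx] <- draw_categorical(m, cl$deprivation)
    bmi <- round(stats::rnorm(m, cl$bmi$mean, cl$bmi$sd), 1)
    bmi[stats::runif(m) < cl$bmi$prop_missing] <- NA_real_
    covariates$bmi[idx] <- bmi
    covariates$smoking[idx] <- draw_categorical(m, cl$smoking)
    covariates$alcohol[idx] <- draw_categorical(m, cl$alcohol)
    covariates$on_glucose_lowering_med[idx] <- stats::runif(m) < cl$med_prob
    for (cm in names(cl$comorbidity)) {
      covariates[[cm]][idx] <- stats::runif(m) < cl$comorbidity[[cm]]
    }
  }

  # long table skeleton
  N <- sum(n_visits)
  pid_row <- rep.int(seq_len(n), n_visits)
  first_row <- c(TRUE, diff(pid_row) != 0L)

  # dates: first visit uniform in date_range, then iid uniform gaps
  span <- as.integer(config$date_range[2] - config$date_range[1])
  offs <- as.integer(floor(stats::runif(n, 0, span + 1)))
  gaps <- as.integer(floor(stats::runif(
    N, config$visit_spacing_days[1], config$visit_spacing_days[2] + 1)))
  gaps[first_row] <- 0L
  cg <- cumsum(gaps)
  cg <- cg - rep.int(cg[first_row], n_visits)
  date <- config$date_range[1] + offs[pid_row] + cg

  # clean values: Normal(true_mean, cv * true_mean), truncated at > 0
  mu_row <- true_mean[pid_row]
  sd_row <- within_cv[pid_row] * mu_row
  value <- stats::rnorm(N, mu_row, sd_row)
  bad <- which(value <= 0)
  while (length(bad)) {
    value[bad] <- stats::rnorm(length(bad), mu_row[bad], sd_row[bad])
    bad <- bad[value[bad] <= 0]
  }

  er <- config$error_rates

  # identical-run patients: all results collapse to one value (reported
  # resolution 0.1 mmol/mol); only patients with >= 4 visits can trigger the
  # downstream exclusion rule, so only those are eligible
  eligible <- which(n_visits >= 4L)
  identical_run <- rep(FALSE, n)
  if (er$identical_run > 0 && length(eligible)) {
    identical_run[eligible] <- stats::runif(length(eligible)) < er$identical_run
    hit <- identical_run[pid_row]
    value[hit] <- round(mu_row[hit], 1)
  }

  # percent values mis-recorded as mmol/mol
  modifiable <- !identical_run[pid_row]
  pct_err <- rep(FALSE, N)
  if (er$percent_unit_error > 0) {
    pct_err <- modifiable & stats::runif(N) < er$percent_unit_error
    value[pct_err] <- pmin(pmax(stats::rnorm(sum(pct_err), 7.7, 1.2), 3), 15)
  }

  # implausibly high values
  high_err <- rep(FALSE, N)
  if (er$implausible_high > 0) {
    high_err <- modifiable & !pct_err & stats::runif(N) < er$implausible_high
    value[high_err] <- stats::runif(sum(high_err), 200, 400)
  }

  cohort <- tibble::tibble(
    record_id = seq_len(N),
    patient_id = patient_id[pid_row],
    date = date,
    value = value,
    unit = "mmol/mol"
  )
  flags <- tibble::tibble(
    record_id = seq_len(N),
    patient_id = patient_id[pid_row],
    percent_unit_error = pct_err,
    implausible_high = high_err,
    duplicate = FALSE
  )

  # same-day duplicates, appended after the originals so that the original
  # is "first in input order" within its (patient, date) group
  if (er$same_day_duplicate > 0) {
    dup <- which(stats::runif(N) < er$same_day_duplicate)
    if (length(dup)) {
      dups <- cohort[dup, ]
      dups$record_id <- N + seq_along(dup)
      cohort <- dplyr::bind_rows(cohort, dups)
      flags <- dplyr::bind_rows(flags, tibble::tibble(
        record_id = dups$record_id,
        patient_id = dups$patient_id,
        percent_unit_error = pct_err[dup],
        implausible_high = high_err[dup],
        duplicate = TRUE
      ))
    }
  }

  truth <- structure(
    list(
      patients = tibble::tibble(
        patient_id = patient_id,
        stratum = vapply(strata, `[[`, character(1), "label")[stratum_idx],
        true_mean = true_mean,
        within_cv = within_cv,
        n_visits = n_visits,
        identical_run = identical_run
      ),
      record_flags = flags,
      config = config
    ),
    class = "truth_record"
  )

  list(cohort = cohort, covariates = covariates, truth = truth)
}

#' Summarise the latent truth of a synthetic cohort
#'
#' @param truth A `truth_record` from [generate_cohort()].
#'
#' @return A tibble with one row per stratum: patient count, mean of the
#'   latent true means, mean within-patient CV, and counts of injected
#'   errors (identical-run patients; percent-unit, implausible-high and
#'   duplicate records).
#' @export
truth_summary <- function(truth) {
  if (!inherits(truth, "truth_record")) {
    stop("truth_summary: `truth` must come from generate_cohort()", call. = FALSE)
  }
  pats <- truth$patients
  flags <- dplyr::left_join(truth$record_flags,
                            pats[, c("patient_id", "stratum")],
                            by = "patient_id")
  err <- flags |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_percent_error_records = sum(.data$percent_unit_error),
      n_implausible_records = sum(.data$implausible_high),
      n_duplicate_records = sum(.data$duplicate),
      .groups = "drop"
    )
  pats |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      mean_true_mean = mean(.data$true_mean),
      mean_within_cv = mean(.data$within_cv),
      n_identical_run_patients = sum(.data$identical_run),
      .groups = "drop"
    ) |>
    dplyr::left_join(err, by = "stratum")
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record> ", nrow(x$patients), " patients, ",
      nrow(x$record_flags), " records\n", sep = "")
  print(truth_summary(x))
  invisible(x)
}
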