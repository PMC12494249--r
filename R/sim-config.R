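#' Specify one diabetic-status stratum of a synthetic cohort
#'
#' A stratum bundles the latent distribution of patient-level true mean HbA1c
#' with the within-patient measurement coefficient of variation (CV) and the
#' categorical laws used to draw covariates. Strata are combined by
#' [sim_config()] with mixing weights.
#'
#' @param label Stratum label, one of `"none"`, `"prediabetes"`, `"T1DM"`,
#'   `"T2DM"` (other labels are allowed for custom cohorts).
#' @param weight Fraction of the cohort drawn from this stratum (weights of
#'   all strata must sum to 1).
#' @param true_mean_center Centre of the between-patient distribution of true
#'   mean HbA1c, mmol/mol. Must be positive.
#' @param true_mean_sd Between-patient standard deviation of the true means,
#'   mmol/mol. `0` gives all patients the same true mean.
#' @param within_cv Within-patient measurement CV as a dimensionless fraction
#'   (the SD of repeated results is `within_cv * true_mean`).
#' @param covariate_laws Named list of covariate distributions as produced by
#'   [default_covariate_laws()]; individual entries may be overridden.
#'
#' @return An object of class `stratum_spec`.
#' @seealso [sim_config()], [default_strata()]
#' @export
stratum_spec <- function(label, weight, true_mean_center, true_mean_sd,
                         within_cv, covariate_laws = default_covariate_laws()) {
  if (!is.character(label) || length(label) != 1L) {
    stop("stratum_spec: `label` must be a single string", call. = FALSE)
  }
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0) {
    stop("stratum_spec: `weight` must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(true_mean_center) || true_mean_center <= 0) {
    stop("stratum_spec: `true_mean_center` must be > 0", call. = FALSE)
  }
  if (!is.numeric(true_mean_sd) || true_mean_sd < 0) {
    stop("stratum_spec: `true_mean_sd` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(within_cv) || within_cv < 0) {
    stop("stratum_spec: `within_cv` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      label = label, weight = weight,
      true_mean_center = true_mean_center, true_mean_sd = true_mean_sd,
      within_cv = within_cv, covariate_laws = covariate_laws
    ),
    class = "stratum_spec"
  )
}

#' Default covariate distributions for synthetic patients
#'
#' Categorical probabilities approximate the marginal composition of a large
#' UK primary-care HbA1c cohort: 51.7% male; ethnicity dominated by White
#' records with ~40% missing; Townsend deprivation quintiles with ~19%
#' missing; age centred in the late 60s; BMI centred near 28 kg/m^2.
#'
#' @param sex Named probabilities for `male`/`female`.
#' @param ethnicity Named probabilities over ethnicity categories (including
#'   `Missing`).
#' @param deprivation Named probabilities over Townsend quintiles `1`..`5`
#'   and `Missing`.
#' @param smoking,alcohol Named probabilities over lifestyle categories.
#' @param age List with `mean`, `sd`, `min`, `max` for a truncated normal age
#'   at first measurement, years.
#' @param bmi List with `mean`, `sd` and `prop_missing` for BMI, kg/m^2.
#' @param med_prob Probability a patient is flagged as using
#'   glucose-lowering medication.
#' @param comorbidity Named probabilities for binary comorbidity flags.
#'
#' @return A named list of covariate laws.
#' @export
default_covariate_laws <- function(
    sex = c(male = 0.517, female = 0.483),
    ethnicity = c(White = 0.518, `South Asian` = 0.043, Black = 0.019,
                  Mixed = 0.004, Others = 0.014, Missing = 0.402),
    deprivation = c(`1` = 0.176, `2` = 0.169, `3` = 0.177, `4` = 0.164,
                    `5` = 0.124, Missing = 0.190),
    smoking = c(never = 0.45, ex = 0.35, current = 0.20),
    alcohol = c(current = 0.55, ex = 0.15, never = 0.30),
    age = list(mean = 67, sd = 15, min = 5, max = 102),
    bmi = list(mean = 28.5, sd = 5.5, prop_missing = 0.05),
    med_prob = 0.0,
    comorbidity = c(hypertension = 0.40, ihd = 0.15, cancer = 0.10)) {
  list(sex = sex, ethnicity = ethnicity, deprivation = deprivation,
       smoking = smoking, alcohol = alcohol, age = age, bmi = bmi,
       med_prob = med_prob, comorbidity = comorbidity)
}

#' Default four-stratum cohort by diabetic status
#'
#' Mixing weights, mean HbA1c and within-patient CV per stratum follow the
#' published marginal profile of a large UK primary-care cohort: no diabetes
#' (25.4% of patients, mean 38.24 mmol/mol, CV 0.091), prediabetes (12.6%,
#' 48.74, 0.180), type 1 diabetes (5.7%, 70.17, 0.157) and type 2 diabetes
#' (56.3%, 58.70, 0.194). Between-patient SDs of the true means are not
#' published for such cohorts and are package defaults chosen to give
#' clinically plausible spreads within each status group.
#'
#' @return A list of four [stratum_spec()] objects.
#' @export
default_strata <- function() {
  list(
    stratum_spec("none", 0.2545, 38.24, 4, 0.091,
                 covariate_laws = default_covariate_laws(med_prob = 0.01)),
    stratum_spec("prediabetes", 0.1259, 48.74, 3, 0.180,
                 covariate_laws = default_covariate_laws(med_prob = 0.05)),
    stratum_spec("T1DM", 0.0571, 70.17, 13, 0.157,
                 covariate_laws = default_covariate_laws(
                   med_prob = 1, age = list(mean = 45, sd = 18, min = 5, max = 102))),
    stratum_spec("T2DM", 0.5625, 58.70, 12, 0.194,
                 covariate_laws = default_covariate_laws(med_prob = 0.70))
  )
}

#' Configure a synthetic longitudinal HbA1c cohort
#'
#' Collects everything [generate_cohort()] needs: the stratum mixture, the
#' law for the number of visits per patient (default: a discretised
#' log-normal whose median is 11 visits with interquartile range 7-18,
#' matching routinely collected HbA1c testing frequency), visit spacing, the
#' calendar window, and the rates at which the generator injects the
#' characteristic recording errors of EHR laboratory data:
#'
#' * `percent_unit_error`: fraction of records whose value is replaced by an
#'   NGSP percentage (normal around 7.7, clipped to 3-15) while still tagged
#'   mmol/mol — the "percent recorded as mmol/mol" error mode.
#' * `same_day_duplicate`: fraction of records duplicated on the same date.
#' * `implausible_high`: fraction of records replaced by an implausible value
#'   above 195.1 mmol/mol.
#' * `identical_run`: fraction of patients (among those with at least four
#'   visits) whose results are all set to one identical value, emulating
#'   duplicated-result artefacts.
#'
#' @param n_patients Number of patients, at least 1.
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @param strata List of [stratum_spec()]; weights must sum to 1.
#' @param visit_count_law List with `meanlog`, `sdlog` and `min` for the
#'   discretised log-normal visit-count law.
#' @param visit_spacing_days Length-2 integer vector, uniform bounds (days)
#'   for the gap between consecutive visits.
#' @param error_rates Named list of the four injection rates, each in
#'   \[0, 1\].
#' @param date_range Length-2 `Date` vector; first visits are uniform in this
#'   window.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       strata = default_strata(),
                       visit_count_law = list(meanlog = log(11), sdlog = 0.700, min = 1L),
                       visit_spacing_days = c(30L, 365L),
                       error_rates = list(percent_unit_error = 0, same_day_duplicate = 0,
                                          implausible_high = 0, identical_run = 0),
                       date_range = as.Date(c("2010-01-01", "2019-12-31"))) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("sim_config: `n_patients` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("sim_config: `seed` must be a finite integer", call. = FALSE)
  }
  if (!is.list(strata) || length(strata) < 1L ||
      !all(vapply(strata, inherits, logical(1), "stratum_spec"))) {
    stop("sim_config: `strata` must be a non-empty list of stratum_spec objects",
         call. = FALSE)
  }
  w <- vapply(strata, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) {
    stop("sim_config: `strata` weights must sum to 1 (got ", signif(sum(w), 6), ")",
         call. = FALSE)
  }
  need <- c("percent_unit_error", "same_day_duplicate", "implausible_high",
            "identical_run")
  miss <- setdiff(need, names(error_rates))
  if (length(miss)) {
    stop("sim_config: `error_rates` is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) {
    r <- error_rates[[nm]]
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1) {
      stop("sim_config: `error_rates$", nm, "` must be in [0, 1]", call. = FALSE)
    }
  }
  if (!all(c("meanlog", "sdlog", "min") %in% names(visit_count_law))) {
    stop("sim_config: `visit_count_law` needs meanlog, sdlog and min", call. = FALSE)
  }
  if (visit_count_law$sdlog < 0 || visit_count_law$min < 1) {
    stop("sim_config: `visit_count_law` must have sdlog >= 0 and min >= 1",
         call. = FALSE)
  }
  if (length(visit_spacing_days) != 2L || any(visit_spacing_days < 1) ||
      visit_spacing_days[1] > visit_spacing_days[2]) {
    stop("sim_config: `visit_spacing_days` must be increasing positive bounds",
         call. = FALSE)
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || any(is.na(date_range)) ||
      date_range[1] > date_range[2]) {
    stop("sim_config: `date_range` must be two ordered dates", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         strata = strata, visit_count_law = visit_count_law,
         visit_spacing_days = as.integer(visit_spacing_days),
         error_rates = error_rates, date_range = date_range),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_patients, " patients, seed ", x$seed, "\n", sep = "")
  for (s in x$strata) {
    cat(sprintf("  stratum %-12s w=%.4f  mean %.2f (sd %.1f)  within CV %.3f\n",
                s$label, s$weight, s$true_mean_center, s$true_mean_sd, s$within_cv))
  }
  er <- unlist(x$error_rates)
  cat("  error rates:", paste(names(er), signif(er, 3), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
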