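# Shared fixtures, all built in code.

# Three patients with two results each: within-variance 8, grand mean 52,
# CV = sqrt(8)/52 by hand ANOVA.
make_toy_cohort <- function() {
  tibble::tibble(
    patient_id = rep(c("A", "B", "C"), each = 2L),
    date = rep(as.Date("2020-01-01") + c(0, 30), 3L),
    value = c(40, 44, 50, 54, 60, 64),
    unit = "mmol/mol"
  )
}

# Worked cleaning fixture: every cascade rule fires exactly once.
# P1 survives with 4 records after a same-day duplicate is dropped;
# P2 loses a percent-tagged, a too-low and a too-high record and then fails
# the minimum-measurement rule; P3 has one identical value on 4 dates.
make_cleaning_fixture <- function() {
  cohort <- tibble::tibble(
    patient_id = c(rep("P1", 5), rep("P2", 4), rep("P3", 4)),
    date = as.Date(c(
      "2015-01-01", "2015-02-01", "2015-03-01", "2015-04-01", "2015-04-01",
      "2015-01-10", "2015-02-10", "2015-03-10", "2015-04-10",
      "2015-01-05", "2015-02-05", "2015-03-05", "2015-04-05"
    )),
    value = c(50, 52.3, 49.8, 55, 51, 7.7, 6.5, 210, 48, 52, 52, 52, 52),
    unit = c(rep("mmol/mol", 6), "percent", rep("mmol/mol", 6))
  )
  covariates <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    age = c(70L, 55L, 63L),
    sex = c("male", "female", "male"),
    bmi = c(25, 12, NA)
  )
  expected <- list(
    records_in = 13L, patients_in = 3L,
    records_removed = c(unit = 1L, low = 1L, high = 1L,
                        same_day_duplicate = 1L, identical_results = 4L,
                        too_few_measurements = 1L),
    patients_removed = c(unit = 0L, range = 0L, same_day_duplicate = 0L,
                         identical_results = 1L, too_few_measurements = 1L),
    bmi_recoded_missing = 1L,
    records_out = 4L, patients_out = 1L
  )
  list(cohort = cohort, covariates = covariates, expected = expected)
}

# One-stratum generator config with a fixed number of visits per patient.
single_stratum_config <- function(n_patients, within_cv, seed,
                                  mean_center = 52.31, mean_sd = 0,
                                  visits = 10L,
                                  error_rates = list(percent_unit_error = 0,
                                                     same_day_duplicate = 0,
                                                     implausible_high = 0,
                                                     identical_run = 0)) {
  sim_config(
    n_patients, seed = seed,
    strata = list(stratum_spec("s", 1, mean_center, mean_sd, within_cv)),
    visit_count_law = list(meanlog = log(visits), sdlog = 0, min = visits),
    error_rates = error_rates
  )
}
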