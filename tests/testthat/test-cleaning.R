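test_that("the worked fixture yields the hand-derived cleaning report", {
  fx <- make_cleaning_fixture()
  res <- clean_cohort(fx$cohort, fx$covariates)
  rep <- res$report
  expect_identical(rep$records_in, fx$expected$records_in)
  expect_identical(rep$patients_in, fx$expected$patients_in)
  expect_identical(as.integer(rep$records_removed),
                   as.integer(fx$expected$records_removed))
  expect_identical(names(rep$records_removed),
                   names(fx$expected$records_removed))
  expect_identical(as.integer(rep$patients_removed),
                   as.integer(fx$expected$patients_removed))
  expect_identical(rep$bmi_recoded_missing, fx$expected$bmi_recoded_missing)
  expect_identical(rep$records_out, fx$expected$records_out)
  expect_identical(rep$patients_out, fx$expected$patients_out)
  # surviving patient keeps the first record of the duplicated day
  kept <- res$cohort[res$cohort$date == as.Date("2015-04-01"), ]
  expect_identical(kept$value, 55)
  # BMI 12 recoded missing, BMI 25 untouched
  expect_true(is.na(res$covariates$bmi[res$covariates$patient_id == "P2"]))
  expect_identical(res$covariates$bmi[res$covariates$patient_id == "P1"], 25)
})

test_that("the shipped fixture files match the in-code fixture", {
  fx <- make_cleaning_fixture()
  res_file <- system.file("extdata", "cleaning_fixture_results.csv",
                          package = "hba1cvar")
  cov_file <- system.file("extdata", "cleaning_fixture_covariates.csv",
                          package = "hba1cvar")
  cohort <- readr::read_csv(res_file, show_col_types = FALSE)
  covs <- readr::read_csv(cov_file, show_col_types = FALSE)
  expect_equal(as.data.frame(cohort), as.data.frame(fx$cohort))
  expect_equal(as.data.frame(covs), as.data.frame(fx$covariates))
})

test_that("range boundaries are kept under strict inequalities", {
  cohort <- tibble::tibble(
    patient_id = "X", date = as.Date("2020-01-01") + 0:4,
    value = c(7.7, 20.1, 52, 195.1, 200), unit = "mmol/mol"
  )
  out <- filter_range(cohort)
  expect_identical(out$cohort$value, c(20.1, 52, 195.1))
  expect_identical(out$removed_low, 1L)
  expect_identical(out$removed_high, 1L)
  empty <- filter_range(cohort[0, ])
  expect_identical(nrow(empty$cohort), 0L)
  expect_identical(empty$removed_low + empty$removed_high, 0L)
})

test_that("same-day deduplication keeps the first record in input order", {
  cohort <- tibble::tibble(
    patient_id = "X", date = as.Date("2020-05-05"),
    value = c(41, 42, 43), unit = "mmol/mol"
  )
  out <- dedupe_same_day(cohort)
  expect_identical(out$cohort$value, 41)
  expect_identical(out$removed, 2L)
  distinct <- tibble::tibble(patient_id = "X",
                             date = as.Date("2020-01-01") + 0:2,
                             value = c(41, 42, 43), unit = "mmol/mol")
  expect_identical(dedupe_same_day(distinct)$removed, 0L)
})

test_that("identical-run exclusion needs the full run of distinct dates", {
  below <- tibble::tibble(
    patient_id = "X", date = as.Date("2020-01-01") + 0:5,
    value = c(52, 52, 52, 48, 50, 55), unit = "mmol/mol"
  )
  expect_identical(drop_identical_runs(below)$removed_patients, 0L)
  at <- below
  at$value[4] <- 52
  out <- drop_identical_runs(at)
  expect_identical(out$removed_patients, 1L)
  expect_identical(nrow(out$cohort), 0L)
  # equality is at the 0.1 mmol/mol reporting resolution
  rounded <- below
  rounded$value <- c(52.04, 51.96, 52.01, 52.02, 44, 45)
  expect_identical(drop_identical_runs(rounded)$removed_patients, 1L)
})

test_that("unit filtering can push a patient under the measurement floor", {
  cohort <- tibble::tibble(
    patient_id = "M", date = as.Date("2020-01-01") + 0:4,
    value = c(50, 51, 6.4, 6.5, 52),
    unit = c("mmol/mol", "mmol/mol", "percent", "percent", "mmol/mol")
  )
  res <- clean_cohort(cohort)
  expect_identical(res$report$records_removed[["unit"]], 2L)
  expect_identical(res$report$records_removed[["too_few_measurements"]], 3L)
  expect_identical(res$report$patients_removed[["too_few_measurements"]], 1L)
  expect_identical(res$report$patients_out, 0L)
  expect_error(filter_unit(tibble::tibble(patient_id = "a",
                                          date = as.Date("2020-01-01"),
                                          value = 50, unit = "mg/dl")),
               "unknown unit")
})

test_that("BMI recoding uses strict bounds and counts recodes", {
  covs <- tibble::tibble(patient_id = letters[1:6],
                         bmi = c(13.9, 14, 70, 70.1, 25, NA))
  out <- recode_bmi(covs)
  expect_identical(out$recoded, 2L)
  expect_identical(out$covariates$bmi, c(NA, 14, 70, NA, 25, NA))
})

test_that("cleaning conserves records and patients on synthetic cohorts", {
  cfg <- sim_config(400, seed = 31,
                    error_rates = list(percent_unit_error = 0.04,
                                       same_day_duplicate = 0.05,
                                       implausible_high = 0.02,
                                       identical_run = 0.05))
  g <- generate_cohort(cfg)
  res <- clean_cohort(g$cohort, g$covariates)
  rep <- res$report
  expect_identical(rep$records_in,
                   rep$records_out + sum(rep$records_removed))
  expect_identical(rep$patients_in,
                   rep$patients_out + sum(rep$patients_removed))
  # error modes that cannot occur in this cohort leave zero counts
  expect_identical(rep$records_removed[["unit"]], 0L)
  # modes that were injected are caught
  expect_gt(rep$records_removed[["same_day_duplicate"]], 0L)
  expect_gt(rep$records_removed[["low"]], 0L)
  expect_gt(rep$records_removed[["high"]], 0L)
  expect_gte(rep$patients_removed[["identical_results"]],
             sum(g$truth$patients$identical_run))
})

test_that("cleaning is idempotent", {
  cfg <- sim_config(300, seed = 41,
                    error_rates = list(percent_unit_error = 0.05,
                                       same_day_duplicate = 0.05,
                                       implausible_high = 0.02,
                                       identical_run = 0.03))
  g <- generate_cohort(cfg)
  once <- clean_cohort(g$cohort, g$covariates)
  twice <- clean_cohort(once$cohort, once$covariates)
  expect_identical(sum(twice$report$records_removed), 0L)
  expect_identical(sum(twice$report$patients_removed), 0L)
  expect_identical(twice$report$bmi_recoded_missing, 0L)
  expect_equal(as.data.frame(twice$cohort), as.data.frame(once$cohort))
})

test_that("a cohort in which every patient fails cleans to empty with conserved totals", {
  cohort <- tibble::tibble(
    patient_id = rep(c("A", "B"), each = 4L),
    date = rep(as.Date("2020-01-01") + 0:3, 2L),
    value = rep(c(52, 61), each = 4L),
    unit = "mmol/mol"
  )
  res <- clean_cohort(cohort)
  expect_identical(res$report$records_out, 0L)
  expect_identical(res$report$patients_out, 0L)
  expect_identical(res$report$records_in, sum(res$report$records_removed))
  expect_identical(res$report$patients_in, sum(res$report$patients_removed))
})
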