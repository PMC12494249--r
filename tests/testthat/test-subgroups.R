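test_that("per-patient features are computed as stated", {
  cohort <- tibble::tibble(
    patient_id = rep("p", 3),
    date = as.Date("2020-01-01") + c(0, 100, 200),
    value = c(40, 50, 60), unit = "mmol/mol"
  )
  f <- derive_features(cohort)
  expect_equal(f$median_gap_days, 100)
  expect_equal(f$mean_hba1c, 50)
  expect_equal(f$median_hba1c, 50)
  expect_identical(f$n_measurements, 3L)
  expect_identical(bmi_band(c(25, 18.5, 35, 17, NA)),
                   c("25 to <30", "18.5 to <25", ">35", "<18.5", "Missing"))
  expect_identical(age_band(c(10, 11, 70, 101)),
                   c("<=10", "11-20", "61-70", ">100"))
})

test_that("a spec covering everyone reproduces the whole-cohort CV", {
  g <- generate_cohort(single_stratum_config(150, 0.15, seed = 8,
                                             mean_sd = 5, visits = 5L))
  covs <- g$covariates
  covs$everyone <- "all"
  res <- stratified_cv(g$cohort, subgroup_spec("everyone"), covs,
                       engine = "moments")
  whole <- cv_model(g$cohort, engine = "moments")
  expect_identical(nrow(res), 1L)
  expect_equal(res$cv, whole$cv, tolerance = 1e-12)
  expect_identical(res$n_patients, 150L)
})

test_that("stratified estimation recovers distinct within-CVs per stratum", {
  cfg <- sim_config(
    4000, seed = 19,
    strata = list(
      stratum_spec("low", 0.5, 40, 4, 0.09),
      stratum_spec("high", 0.5, 58, 6, 0.19)
    ),
    visit_count_law = list(meanlog = log(8), sdlog = 0, min = 8L)
  )
  g <- generate_cohort(cfg)
  res <- stratified_cv(g$cohort, subgroup_spec("diabetic_status"),
                       g$covariates, engine = "moments")
  lo <- res[res$stratum == "low", ]
  hi <- res[res$stratum == "high", ]
  expect_lt(abs(lo$cv - 0.09), 0.015)
  expect_lt(abs(hi$cv - 0.19), 0.015)
  pooled <- cv_model(g$cohort, engine = "moments")
  expect_gt(pooled$cv, lo$cv)
  # partition property: stratum patients sum to the cohort
  expect_identical(sum(res$n_patients), 4000L)
})

test_that("strata below the participant floor are suppressed without estimates", {
  g <- generate_cohort(single_stratum_config(160, 0.12, seed = 23,
                                             mean_sd = 5, visits = 5L))
  covs <- g$covariates
  covs$flag <- rep(c("big", "small"), c(61, 99))
  res <- stratified_cv(g$cohort, subgroup_spec("flag"), covs,
                       engine = "moments")
  small <- res[res$stratum == "small", ]
  expect_true(small$suppressed)
  expect_true(is.na(small$cv))
  expect_identical(small$n_patients, 99L)
  big <- res[res$stratum == "big", ]
  expect_true(big$suppressed) # 61 < 100 too
  lax <- stratified_cv(g$cohort, subgroup_spec("flag", min_group_size = 50),
                       covs, engine = "moments")
  expect_false(any(lax$suppressed))
})

test_that("unknown variables are a specification error", {
  g <- generate_cohort(single_stratum_config(20, 0.1, seed = 2, visits = 4L))
  expect_error(stratified_cv(g$cohort, subgroup_spec("no_such_column"),
                             g$covariates),
               "unknown variable")
})

test_that("numeric features can be binned through spec breaks", {
  g <- generate_cohort(single_stratum_config(300, 0.15, seed = 29,
                                             mean_sd = 8, visits = 5L))
  res <- stratified_cv(g$cohort,
                       subgroup_spec("mean_hba1c", breaks = c(45, 55),
                                     min_group_size = 10),
                       engine = "moments")
  expect_setequal(res$stratum, c("[-Inf,45)", "[45,55)", "[55, Inf)"))
  expect_identical(sum(res$n_patients), 300L)
})

test_that("record-level status stratification honours the segment rule", {
  cohort <- tibble::tibble(
    patient_id = c(rep("p1", 7), rep("p2", 4)),
    date = c(as.Date("2020-01-01") + (0:6) * 30,
             as.Date("2020-01-01") + (0:3) * 30),
    value = c(rnorm(7, 50, 2), rnorm(4, 60, 2)),
    unit = "mmol/mol",
    status = c(rep("A", 4), rep("B", 3), rep("A", 4))
  )
  res <- stratified_cv(cohort, subgroup_spec("status", min_group_size = 2),
                       engine = "moments")
  a <- res[res$stratum == "A", ]
  # p1 contributes only its 4-record A segment; its 3-record B segment and
  # no B stratum at all survive the 4-record floor
  expect_identical(a$n_patients, 2L)
  expect_identical(a$n_records, 8L)
  expect_false("B" %in% res$stratum)
})

test_that("cross-classification conserves patients and matches brute-force cells", {
  cfg <- sim_config(
    600, seed = 37,
    strata = list(
      stratum_spec("none", 0.5, 38, 4, 0.09),
      stratum_spec("T2DM", 0.5, 59, 8, 0.19)
    ),
    visit_count_law = list(meanlog = log(6), sdlog = 0, min = 6L)
  )
  g <- generate_cohort(cfg)
  res <- cross_classified_cv(
    g$cohort,
    list(subgroup_spec("sex", min_group_size = 50),
         subgroup_spec("diabetic_status", min_group_size = 50)),
    g$covariates, engine = "moments"
  )
  expect_identical(nrow(res), 4L) # 2 sexes x 2 statuses
  expect_identical(sum(res$n_patients) + attr(res, "n_excluded_missing"),
                   600L)
  # brute-force recount of one cell
  feats <- derive_features(g$cohort, g$covariates)
  manual <- sum(feats$sex == "male" & feats$diabetic_status == "T2DM")
  expect_identical(res$n_patients[res$sex == "male" &
                                    res$diabetic_status == "T2DM"], manual)
  # a degenerate single-cell spec equals the whole-cohort estimate
  covs <- g$covariates
  covs$one <- "all"
  single <- cross_classified_cv(g$cohort,
                                list(subgroup_spec("one", min_group_size = 2)),
                                covs, engine = "moments")
  expect_equal(single$cv, cv_model(g$cohort, engine = "moments")$cv,
               tolerance = 1e-12)
  expect_error(cross_classified_cv(g$cohort, list(), g$covariates), "specs")
})
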