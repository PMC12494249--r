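test_that("the hand-worked toy gives the ANOVA values on both engines", {
  toy <- make_toy_cohort()
  m <- fit_components_moments(toy)
  expect_equal(m$within_sd^2, 8)
  expect_equal(m$grand_mean, 52)
  r <- fit_components_reml(toy)
  expect_equal(r$within_sd, m$within_sd, tolerance = 1e-6)
  expect_equal(r$between_sd, m$between_sd, tolerance = 1e-6)
  est <- cv_from_components(m)
  expect_equal(est$cv, sqrt(8) / 52, tolerance = 1e-12)
  expect_lt(est$ci_low, est$cv)
  expect_gt(est$ci_high, est$cv)
})

test_that("REML equals the moment estimator on balanced interior designs", {
  set.seed(101)
  for (rep in 1:5) {
    k <- sample(20:60, 1)
    m <- sample(3:8, 1)
    # large between-variance keeps the solution interior
    mu_i <- rnorm(k, 55, 10)
    cohort <- tibble::tibble(
      patient_id = rep(sprintf("p%02d", 1:k), each = m),
      value = rnorm(k * m, rep(mu_i, each = m), 4)
    )
    mo <- fit_components_moments(cohort)
    re <- fit_components_reml(cohort)
    expect_gt(mo$between_sd, 0)
    expect_equal(re$within_sd, mo$within_sd, tolerance = 1e-6)
    expect_equal(re$between_sd, mo$between_sd, tolerance = 1e-6)
  }
})

test_that("REML agrees with an independent mixed-model fitter on unbalanced data", {
  set.seed(7)
  k <- 60
  n_i <- sample(2:9, k, replace = TRUE)
  mu_i <- rnorm(k, 55, 8)
  cohort <- tibble::tibble(
    patient_id = rep(sprintf("p%02d", 1:k), times = n_i),
    value = rnorm(sum(n_i), rep(mu_i, times = n_i), 5)
  )
  ours <- fit_components_reml(cohort)
  fit <- lme4::lmer(value ~ 1 + (1 | patient_id), data = cohort, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(ours$within_sd, vc$sdcor[vc$grp == "Residual"],
               tolerance = 1e-4)
  expect_equal(ours$between_sd, vc$sdcor[vc$grp == "patient_id"],
               tolerance = 1e-4)
  expect_equal(ours$grand_mean, unname(lme4::fixef(fit)[1]), tolerance = 1e-6)
})

test_that("degenerate inputs take their closed-form limits", {
  one <- tibble::tibble(patient_id = "solo", value = c(48, 50, 55))
  vc <- fit_components_moments(one)
  expect_equal(vc$within_sd, sd(one$value))
  expect_equal(vc$between_sd, 0)
  vr <- fit_components_reml(one)
  expect_equal(vr$within_sd, sd(one$value), tolerance = 1e-8)
  expect_equal(vr$between_sd, 0)

  const <- tibble::tibble(patient_id = rep(c("a", "b"), each = 3L),
                          value = rep(c(50, 60), each = 3L))
  expect_equal(fit_components_moments(const)$within_sd, 0)
  expect_lt(fit_components_reml(const)$within_sd, 1e-6)
  est <- cv_from_components(fit_components_moments(const))
  expect_equal(est$cv, 0)
  expect_equal(est$ci_low, 0)

  short <- tibble::tibble(patient_id = c("a", "a", "b"), value = c(1, 2, 3))
  expect_error(fit_components_moments(short), "fewer than 2")
})

test_that("the crude arithmetic CV averages per-patient CVs", {
  toy <- make_toy_cohort()
  est <- cv_crude(toy)
  expect_equal(est$cv, mean(sqrt(8) / c(42, 52, 62)), tolerance = 1e-12)
  const <- tibble::tibble(patient_id = rep("a", 4), value = rep(52, 4))
  expect_equal(cv_crude(const)$cv, 0)
  solo <- tibble::tibble(patient_id = "s", value = c(40, 50))
  expect_equal(cv_crude(solo)$cv, sd(c(40, 50)) / 45)
  neg <- tibble::tibble(patient_id = rep("n", 2), value = c(-1, 1))
  expect_error(cv_crude(neg), "non-positive")
})

test_that("the log-scale CV recovers log-normal within-noise and its small-CV limit", {
  set.seed(33)
  k <- 500; m <- 10
  target <- 0.10
  sdlog <- sqrt(log(1 + target^2))
  mu_i <- exp(rnorm(k, log(52), 0.08))
  cohort <- tibble::tibble(
    patient_id = rep(sprintf("p%03d", 1:k), each = m),
    value = exp(rnorm(k * m, rep(log(mu_i), each = m), sdlog))
  )
  est <- cv_log(cohort, engine = "moments")
  expect_lt(abs(est$cv - target), 0.01)

  # small-CV limit: cv_log ~ sigma_w on the log scale
  logged <- cohort
  logged$value <- log(cohort$value)
  sw_log <- fit_components_moments(logged)$within_sd
  sdlog2 <- sqrt(log(1 + 0.02^2))
  cohort2 <- cohort
  cohort2$value <- exp(rnorm(k * m, rep(log(mu_i), each = m), sdlog2))
  l2 <- cohort2; l2$value <- log(cohort2$value)
  expect_lt(abs(cv_log(cohort2, engine = "moments")$cv -
                  fit_components_moments(l2)$within_sd), 1e-3)

  # zero noise collapses to zero; non-positive values are rejected
  flat <- tibble::tibble(patient_id = rep(c("a", "b"), each = 3L),
                         value = rep(c(50, 60), each = 3L))
  expect_lt(cv_log(flat, engine = "moments")$cv, 1e-8)
  bad <- tibble::tibble(patient_id = rep("a", 2), value = c(0, 5))
  expect_error(cv_log(bad), "positive")
})

test_that("every CV variant is invariant under pure rescaling", {
  set.seed(12)
  cohort <- generate_cohort(single_stratum_config(60, 0.15, seed = 12,
                                                  mean_sd = 5, visits = 6L))$cohort
  scaled <- cohort
  scaled$value <- cohort$value * 3.7
  expect_equal(cv_model(scaled, engine = "moments")$cv,
               cv_model(cohort, engine = "moments")$cv, tolerance = 1e-12)
  expect_equal(cv_model(scaled, engine = "reml")$cv,
               cv_model(cohort, engine = "reml")$cv, tolerance = 1e-9)
  expect_equal(cv_crude(scaled)$cv, cv_crude(cohort)$cv, tolerance = 1e-12)
  expect_equal(cv_log(scaled, engine = "moments")$cv,
               cv_log(cohort, engine = "moments")$cv, tolerance = 1e-12)
})

test_that("confidence intervals narrow as the cohort grows", {
  widths <- vapply(c(40L, 400L, 4000L), function(k) {
    g <- generate_cohort(single_stratum_config(k, 0.20, seed = 77,
                                               mean_sd = 0, visits = 10L))
    est <- cv_from_components(fit_components_moments(g$cohort))
    est$ci_high - est$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the bootstrap interval brackets the estimate", {
  set.seed(55)
  cohort <- generate_cohort(single_stratum_config(80, 0.2, seed = 55,
                                                  mean_sd = 4, visits = 5L))$cohort
  est <- cv_model(cohort, engine = "moments", ci = "bootstrap", n_boot = 200L)
  expect_lt(est$ci_low, est$cv)
  expect_gt(est$ci_high, est$cv)
  chisq <- cv_model(cohort, engine = "moments")
  expect_equal(est$cv, chisq$cv)
  expect_lt(abs((est$ci_high - est$ci_low) - (chisq$ci_high - chisq$ci_low)),
            0.05)
})
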