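# Per-patient sufficient statistics: sizes, means, within sums of squares.
patient_stats <- function(cohort, min_per_patient = 2L) {
  if (nrow(cohort) == 0L) {
    stop("variance components: cohort is empty", call. = FALSE)
  }
  g <- factor(cohort$patient_id)
  n_i <- as.integer(table(g))
  if (any(n_i < min_per_patient)) {
    bad <- levels(g)[which(n_i < min_per_patient)[1]]
    stop("variance components: patient '", bad, "' has fewer than ",
         min_per_patient, " records", call. = FALSE)
  }
  sums <- as.numeric(rowsum(cohort$value, g))
  ybar_i <- sums / n_i
  ssw_i <- as.numeric(rowsum((cohort$value - ybar_i[as.integer(g)])^2, g))
  list(k = nlevels(g), N = nrow(cohort), n_i = n_i, ybar_i = ybar_i,
       ssw_i = ssw_i, grand_mean = mean(cohort$value))
}

new_variance_components <- function(grand_mean, within_sd, between_sd, k, N,
                                    method, extra = list()) {
  structure(
    c(list(grand_mean = grand_mean, within_sd = within_sd,
           between_sd = between_sd, n_patients = k, n_records = N,
           method = method), extra),
    class = "variance_components"
  )
}

#' Method-of-moments variance components for a one-way random-intercept model
#'
#' For repeated measures `y_ij = mu + b_i + e_ij`, estimates the within-
#' patient variance as the pooled within-patient sum of squares divided by
#' `N - k`, and the between-patient variance from the unbalanced one-way
#' ANOVA moment (Henderson) estimator, truncated at zero. This closed-form
#' estimator doubles as the independent oracle against which the REML fit is
#' checked on balanced designs.
#'
#' @param cohort Cleaned lab-record tibble; every patient needs at least two
#'   records.
#'
#' @return A `variance_components` object: `grand_mean`, `within_sd`,
#'   `between_sd`, `n_patients`, `n_records`, `method = "moments"`.
#' @seealso [fit_components_reml()], [cv_from_components()]
#' @export
fit_components_moments <- function(cohort) {
  st <- patient_stats(cohort)
  sw2 <- sum(st$ssw_i) / (st$N - st$k)
  if (st$k > 1L) {
    ssb <- sum(st$n_i * (st$ybar_i - st$grand_mean)^2)
    msb <- ssb / (st$k - 1L)
    n0 <- (st$N - sum(st$n_i^2) / st$N) / (st$k - 1L)
    sb2 <- max(0, (msb - sw2) / n0)
  } else {
    sb2 <- 0
  }
  new_variance_components(st$grand_mean, sqrt(sw2), sqrt(sb2),
                          st$k, st$N, "moments")
}

#' REML variance components for a one-way random-intercept model
#'
#' Maximises the restricted likelihood of `y_ij = mu + b_i + e_ij` over the
#' two variance components. The likelihood is profiled analytically: for a
#' given variance ratio `lambda = sigma_b^2 / sigma_w^2` the restricted-ML
#' within-variance has the closed form `Q(lambda) / (N - 1)`, leaving a
#' one-dimensional search over `log(lambda)` (golden-section, with the
#' boundary `lambda = 0` checked explicitly). Only per-patient sufficient
#' statistics enter the objective, so each evaluation costs O(k). On
#' balanced designs with interior solutions the REML estimates coincide
#' exactly with the ANOVA moment estimates.
#'
#' @inheritParams fit_components_moments
#' @param tol Absolute tolerance on `log(lambda)` for the search.
#' @param max_iter Maximum golden-section iterations; exceeding it is an
#'   error reporting the iteration count and bracket.
#'
#' @return A `variance_components` object with `method = "reml"` plus
#'   `converged`, `iterations` and `logLik_restricted`.
#' @export
fit_components_reml <- function(cohort, tol = 1e-10, max_iter = 200L) {
  st <- patient_stats(cohort)
  # fit on mean-normalised values: lambda is scale-free and the variances
  # back-transform exactly, keeping the CV invariant under rescaling
  scale_ <- abs(st$grand_mean)
  if (scale_ == 0) scale_ <- 1
  st$ybar_i <- st$ybar_i / scale_
  st$ssw_i <- st$ssw_i / scale_^2
  st$grand_mean <- st$grand_mean / scale_
  ssw <- sum(st$ssw_i)

  # profiled -2 restricted log-likelihood (constants dropped) at
  # lambda = exp(ll); sw2 profiled out as Q/(N-1)
  prof <- function(ll) {
    lam <- exp(ll)
    d1 <- 1 + st$n_i * lam
    w <- st$n_i / d1
    mu <- sum(w * st$ybar_i) / sum(w)
    q <- ssw + sum(st$n_i * (st$ybar_i - mu)^2 / d1)
    (st$N - 1) * log(q) + sum(log(d1)) + log(sum(w))
  }

  lo <- -34; hi <- 34 # lambda in [~1e-15, ~6e14]
  if (st$k == 1L) {
    best_ll <- lo # a single patient carries no between-patient information
  } else if (ssw <= 0 || st$N <= st$k) {
    # no within-patient information beyond patient means
    best_ll <- hi
  } else {
    # golden-section search on log(lambda)
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- prof(c1); f2 <- prof(c2)
    iter <- 0L
    while (b - a > tol) {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop("fit_components_reml: no convergence after ", iter - 1L,
             " iterations; bracket [", signif(a, 6), ", ", signif(b, 6),
             "] on log(lambda)", call. = FALSE)
      }
      if (f1 < f2) {
        b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - gr * (b - a); f1 <- prof(c1)
      } else {
        a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + gr * (b - a); f2 <- prof(c2)
      }
    }
    best_ll <- (a + b) / 2
    n_iter <- iter
  }
  if (!exists("n_iter", inherits = FALSE)) n_iter <- 0L

  lam <- exp(best_ll)
  boundary_zero <- best_ll <= lo + 1e-6
  if (boundary_zero) lam <- 0
  d1 <- 1 + st$n_i * lam
  w <- st$n_i / d1
  mu <- sum(w * st$ybar_i) / sum(w)
  q <- ssw + sum(st$n_i * (st$ybar_i - mu)^2 / d1)
  sw2 <- q / (st$N - 1)
  if (st$N == st$k) sw2 <- 0 # one record per patient carries no within info
  sb2 <- lam * sw2
  if (best_ll >= hi - 1e-6 && sw2 < 1e-20) {
    # degenerate zero-within-noise case: all information is between patients
    sb2 <- max(0, fit_components_moments(cohort)$between_sd^2) / scale_^2
    sw2 <- 0
  }
  obj <- if (ssw > 0 && sw2 > 0) {
    (st$N - 1) * log(sw2) + sum(log(d1)) + log(sum(w) / sw2) + (st$N - 1)
  } else NA_real_
  new_variance_components(
    mu * scale_, sqrt(sw2) * scale_, sqrt(sb2) * scale_, st$k, st$N, "reml",
    extra = list(converged = TRUE,
                 iterations = n_iter,
                 logLik_restricted = if (is.na(obj)) NA_real_ else
                   -0.5 * (obj + (st$N - 1) * (log(2 * pi) +
                                                 2 * log(scale_))))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components/%s> mean %.4f | within SD %.4f | between SD %.4f | %d patients, %d records\n",
    x$method, x$grand_mean, x$within_sd, x$between_sd, x$n_patients, x$n_records))
  invisible(x)
}

new_cv_estimate <- function(cv, ci_low, ci_high, level, method, vc = NULL) {
  structure(
    list(cv = cv, ci_low = ci_low, ci_high = ci_high, level = level,
         method = method,
         n_patients = vc$n_patients %||% NA_integer_,
         n_records = vc$n_records %||% NA_integer_,
         mean = vc$grand_mean %||% NA_real_),
    class = "cv_estimate"
  )
}

#' Within-individual CV from fitted variance components
#'
#' The total within-individual coefficient of variation is the within-patient
#' SD divided by the grand mean of all included records. The confidence
#' interval comes from the chi-square distribution of the pooled within-
#' patient variance on `N - k` degrees of freedom, with the mean treated as
#' fixed (its sampling error is negligible at the cohort sizes this interval
#' is used for).
#'
#' @param vc A `variance_components` object.
#' @param level Confidence level, default 0.95.
#'
#' @return A `cv_estimate`: `cv`, `ci_low`, `ci_high`, `level`,
#'   `method = "model"`, with cohort sizes and mean attached.
#' @export
cv_from_components <- function(vc, level = 0.95) {
  if (!inherits(vc, "variance_components")) {
    stop("cv_from_components: `vc` must be a variance_components object",
         call. = FALSE)
  }
  if (vc$grand_mean <= 0) {
    stop("cv_from_components: grand mean must be positive", call. = FALSE)
  }
  df <- vc$n_records - vc$n_patients
  sw2 <- vc$within_sd^2
  alpha <- (1 - level) / 2
  if (df > 0) {
    lo <- sqrt(df * sw2 / stats::qchisq(1 - alpha, df))
    hi <- sqrt(df * sw2 / stats::qchisq(alpha, df))
  } else {
    lo <- 0; hi <- Inf
  }
  new_cv_estimate(vc$within_sd / vc$grand_mean, lo / vc$grand_mean,
                  hi / vc$grand_mean, level, "model", vc)
}

#' Model-based within-individual CV of a cohort
#'
#' Convenience wrapper: fit variance components (REML by default, moments as
#' the closed-form alternative) and convert to a CV with its confidence
#' interval. `ci = "bootstrap"` replaces the chi-square interval with a
#' patient-level nonparametric bootstrap (percentile interval, resampling
#' whole patients), which does not rely on the normal within-patient model.
#'
#' @inheritParams fit_components_moments
#' @param engine `"reml"` or `"moments"`.
#' @param level Confidence level.
#' @param ci `"chisq"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap draws when `ci = "bootstrap"`.
#'
#' @return A `cv_estimate`.
#' @export
cv_model <- function(cohort, engine = c("reml", "moments"), level = 0.95,
                     ci = c("chisq", "bootstrap"), n_boot = 500L) {
  engine <- match.arg(engine)
  ci <- match.arg(ci)
  fit_fun <- if (engine == "reml") fit_components_reml else fit_components_moments
  vc <- fit_fun(cohort)
  est <- cv_from_components(vc, level)
  est$method <- "model"
  if (ci == "bootstrap") {
    ids <- unique(cohort$patient_id)
    rows_by_id <- split(seq_len(nrow(cohort)), cohort$patient_id)[ids]
    cvs <- vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      boot <- cohort[unlist(rows_by_id[take], use.names = FALSE), , drop = FALSE]
      boot$patient_id <- rep.int(seq_along(take),
                                 lengths(rows_by_id[take]))
      v <- fit_fun(boot)
      v$within_sd / v$grand_mean
    }, numeric(1))
    qs <- stats::quantile(cvs, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    est$ci_low <- qs[1]; est$ci_high <- qs[2]
  }
  est
}

#' Crude arithmetic within-individual CV
#'
#' Computes each patient's own CV (sample SD over sample mean) and averages
#' these with the arithmetic mean — the simple sensitivity-analysis
#' alternative to the model-based estimate. The confidence interval is a
#' normal approximation over patients.
#'
#' @inheritParams fit_components_moments
#' @param level Confidence level.
#'
#' @return A `cv_estimate` with `method = "crude"`.
#' @export
cv_crude <- function(cohort, level = 0.95) {
  st <- patient_stats(cohort)
  if (any(st$ybar_i <= 0)) {
    stop("cv_crude: a patient mean is non-positive", call. = FALSE)
  }
  cv_i <- sqrt(st$ssw_i / (st$n_i - 1L)) / st$ybar_i
  cv <- mean(cv_i)
  se <- if (st$k > 1L) stats::sd(cv_i) / sqrt(st$k) else 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  vc <- list(n_patients = st$k, n_records = st$N, grand_mean = st$grand_mean)
  new_cv_estimate(cv, max(0, cv - z * se), cv + z * se, level, "crude", vc)
}

#' Within-individual CV from log-transformed results
#'
#' Fits the variance components on natural-log values and back-transforms
#' the within-patient log-scale variance with
#' `cv = sqrt(exp(sigma_w,log^2) - 1)`, the exact CV of a log-normal
#' within-patient distribution. The interval transforms the chi-square
#' interval of the log-scale variance through the same map.
#'
#' @inheritParams cv_model
#'
#' @return A `cv_estimate` with `method = "log"`.
#' @export
cv_log <- function(cohort, engine = c("reml", "moments"), level = 0.95) {
  engine <- match.arg(engine)
  if (any(cohort$value <= 0)) {
    stop("cv_log: all values must be positive", call. = FALSE)
  }
  logged <- cohort
  logged$value <- log(cohort$value)
  fit_fun <- if (engine == "reml") fit_components_reml else fit_components_moments
  vc <- fit_fun(logged)
  df <- vc$n_records - vc$n_patients
  sw2 <- vc$within_sd^2
  alpha <- (1 - level) / 2
  if (df > 0) {
    lo2 <- df * sw2 / stats::qchisq(1 - alpha, df)
    hi2 <- df * sw2 / stats::qchisq(alpha, df)
  } else {
    lo2 <- 0; hi2 <- Inf
  }
  vc_info <- list(n_patients = vc$n_patients, n_records = vc$n_records,
                  grand_mean = mean(cohort$value))
  new_cv_estimate(sqrt(expm1(sw2)), sqrt(expm1(lo2)), sqrt(expm1(hi2)),
                  level, "log", vc_info)
}

#' @export
print.cv_estimate <- function(x, ...) {
  cat(sprintf("<cv_estimate/%s> CV %.4f (%d%% CI %.4f to %.4f) | %s patients, %s records\n",
              x$method, x$cv, round(100 * x$level), x$ci_low, x$ci_high,
              format(x$n_patients), format(x$n_records)))
  invisible(x)
}
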