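---
title: "Estimating within-individual HbA1c variation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating within-individual HbA1c variation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

HbA1c is reported either on the IFCC scale (mmol/mol) or the NGSP scale (%),
and repeated measurements in the same patient scatter around that patient's
underlying level. The scatter pools three sources — pre-analytical,
analytical and biological variation — which routine data cannot separate;
we therefore estimate the *total* within-individual coefficient of
variation, CV~T~. Everything in this package exists to estimate that
quantity from messy longitudinal laboratory tables, to slice it by patient
characteristics, and to express its clinical consequences as probabilities.

## The model and its estimators

Records are modelled with an intercept-only random-intercept model,

$$y_{ij} = \mu + b_i + e_{ij}, \qquad b_i \sim N(0, \sigma_b^2), \qquad
e_{ij} \sim N(0, \sigma_w^2),$$

and $\mathrm{CV_T} = \sigma_w/\mu$ as a decimal fraction.

Two estimators of the components are provided and are deliberately kept
independent of each other:

* **Moment (ANOVA) estimator** — `fit_components_moments()`. The pooled
  within-patient variance $\hat\sigma_w^2 = \sum_i\sum_j (y_{ij}-\bar
  y_i)^2 / (N-k)$ and the unbalanced one-way moment estimator of
  $\sigma_b^2$ (truncated at zero). Closed form; serves as the oracle.
* **REML** — `fit_components_reml()`. The restricted likelihood is profiled
  analytically: for a fixed variance ratio $\lambda = \sigma_b^2 /
  \sigma_w^2$ the REML within-variance is $Q(\lambda)/(N-1)$ in closed
  form, leaving a one-dimensional search over $\log\lambda$. We use
  golden-section search on $\log\lambda \in [-34, 34]$ (absolute tolerance
  $10^{-10}$, capped at 200 iterations, boundary $\lambda = 0$ checked
  explicitly), with values normalised by the grand mean first so the fit is
  scale-free. On balanced designs with interior solutions REML equals the
  ANOVA estimator exactly, which the tests verify to below $10^{-6}$
  relative; on unbalanced data the fit is cross-checked against
  `lme4::lmer()`.

The **denominator** of CV~T~ is the grand mean of all included records (the
intercept of an observation-level fit), not the mean of patient means. With
unbalanced visit counts the two differ slightly; the grand mean matches the
model intercept interpretation and is used throughout.

Two sensitivity-analysis variants mirror common practice:

* `cv_crude()` — each patient's own $s_i/\bar y_i$, averaged arithmetically
  over patients. This weights every patient equally regardless of visit
  count and is biased slightly low relative to the model estimate.
* `cv_log()` — components fitted on $\log y$, back-transformed as
  $\sqrt{e^{\sigma_{w,\log}^2}-1}$, the exact CV of a log-normal
  within-patient law. For small CVs this reduces to $\sigma_{w,\log}$.

### Confidence intervals

The default interval treats $\mu$ as fixed and uses the chi-square
distribution of $(N-k)\hat\sigma_w^2/\sigma_w^2$:

$$\left[\sqrt{\tfrac{(N-k)\hat\sigma_w^2}{\chi^2_{1-\alpha/2,\,N-k}}},\;
\sqrt{\tfrac{(N-k)\hat\sigma_w^2}{\chi^2_{\alpha/2,\,N-k}}}\right] \Big/ \hat\mu.$$

Ignoring the sampling error of $\hat\mu$ makes the interval slightly
anti-conservative: at 2000 patients × 10 visits the simulated coverage is
about 94% rather than 95%, which the acceptance tests bound inside 93–97%.
A patient-level nonparametric bootstrap (`cv_model(..., ci = "bootstrap")`,
default 500 draws) is exposed as an alternative that does not rely on the
normal within-patient model. The exact interval construction used by
commercial mixed-model software is not replicated.

## The synthetic cohort generator

Real primary-care HbA1c extracts cannot be redistributed, so the generator
is a first-class module that emulates their statistical structure:

* **Strata.** Four diabetic-status strata with the marginal profile of a
  large UK primary-care cohort: none (weight 0.2545, mean 38.24 mmol/mol,
  within-CV 0.091), prediabetes (0.1259, 48.74, 0.180), T1DM (0.0571,
  70.17, 0.157), T2DM (0.5625, 58.70, 0.194). Published profiles do not
  report the *between*-patient SD of true means within a status group, so
  it is a free configuration parameter; the defaults (4, 3, 13 and 12
  mmol/mol) give clinically plausible spreads (non-diabetic levels tightly
  clustered, treated diabetes widely spread) and are not revisited.
* **True means** are Normal per stratum, truncated to (20.1, 195.1).
* **Within-patient noise** is Normal with SD proportional to the true mean
  (constant CV), truncated at zero — the raw-scale CV parameterisation the
  estimators target. A consequence worth knowing: with between-patient
  spread in means, the pooled within-SD equals
  $\mathrm{cv}\sqrt{E[\mu_i^2]}$, so $\hat\sigma_w/\bar y$ recovers the
  generating CV inflated by $\sqrt{1+\sigma_b^2/\mu_0^2}$ — about 0.3% at
  the default spreads, well inside the ±0.01 recovery tolerance. Interval
  *coverage* is therefore assessed under the homogeneous-mean design
  ($\sigma_b = 0$), where the generating CV is exactly the estimand.
* **Visit counts** follow a discretised log-normal with meanlog
  $\log 11$ and sdlog 0.700, matched to a median of 11 visits and IQR 7–18
  (only these quantiles are published; the log-normal is the package's
  choice). Dates start uniformly inside the configured window (default
  2010–2019) with i.i.d. uniform 30–365 day gaps; no trend or seasonality
  is modelled.
* **Error modes**, each at a configurable rate: percent results
  mis-recorded under the mmol/mol tag (Normal around 7.7 with SD 1.2,
  clipped to 3–15 — the published description gives only the 7.7 centre);
  same-day duplicate records (appended after their source so "first in
  input order" keeps the original); implausible highs (uniform 200–400
  mmol/mol); and identical-run patients whose results all collapse to one
  value rounded to 0.1 mmol/mol (only patients with ≥ 4 visits are
  eligible, since shorter runs cannot trigger the exclusion rule).

What the generator deliberately does **not** emulate: disease progression
and medication-driven trends, changes of diabetic status over time,
seasonality, and informative visit frequency (sicker patients being tested
more often — confounding by indication). Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to those real-data features.

## The cleaning cascade

Rules run in a fixed order — unit filter, plausibility range, same-day
deduplication, identical-run exclusion, minimum-measurement floor — chosen
so the patient-level exclusions act on plausible, deduplicated records; the
order is pinned by tests. Numerical conventions, each of which some other
implementation could reasonably make differently:

* Range bounds are **strict** inequalities: 20.1 and 195.1 themselves
  survive (the kept range is "between 20.1 and 195.1").
* "Identical results" are compared after rounding to 0.1 mmol/mol, the
  typical reporting resolution; a patient is removed when any single value
  occurs on at least four distinct dates (not four pairwise-identical
  results in total).
* The "first" result on a duplicated day is the first in file order; no
  intra-day timestamps exist in such extracts.
* BMI outside (14, 70) — again strict — is recoded to a missing category,
  never imputed; unit-error records are excluded, never converted.
* Patients emptied of records by a record-level rule are attributed to that
  rule in the report, so record and patient counts both reconcile exactly.

Note that identical-run exclusions can fire on genuinely clean data: a
stable non-diabetic patient with many visits has a non-trivial chance of
repeating the same rounded value on four dates. This mirrors the behaviour
of the rule on real data and is why zero-injection cohorts may still lose
the odd patient.

## Unit conversion and the CV

NGSP% $= 0.09148 \times$ IFCC $+ 2.152$ (the published master equation;
exposed as configuration since laboratory calibrations differ). Because the
map is affine with a positive intercept, the SD scales by the slope while
the mean also gains the intercept, so the CV computed on converted values
is *strictly smaller* whenever $\sigma_w > 0$ — the CV is not invariant
under this change of units, only under pure rescaling. `cv_under_conversion()`
demonstrates this on any cohort, and the tests assert both directions.

## Subgroups

`stratified_cv()` repeats the estimation on subsets defined by covariates
or derived features (per-patient mean/median HbA1c, median inter-test gap,
measurement count, decade age bands, standard BMI bands). Strata below a
100-participant floor — the conventional compromise between group size and
number of analyses, supported by the precision simulation below — are
reported with counts only and a `suppressed` flag. For a covariate recorded
per result (e.g. diabetic status that changes mid-series), a patient
contributes to a stratum only a segment of at least four results within
that stratum, else is excluded from that analysis. `cross_classified_cv()`
takes the Cartesian product of up to four variables, excludes patients with
missing values in any of them, and applies the floor cellwise. Calendar-year
analyses should be restricted to complete years (2010–2019 in the default
date window). Formal interaction modelling is out of scope.

## Repeat-test transition matrices

`first_second_pairs()` takes each patient's two chronologically earliest
cleaned results. `build_transition_matrix()` bins them (default 5 mmol/mol
bins anchored at the 48 mmol/mol diagnostic cut-point, so a "48 to 53" row
exists) and row-normalises the counts; the MCID exceedance probabilities
per first-result bin are computed from the **raw** pair values, not the
binned ones — binning is display resolution, the clinical question is about
actual differences. The MCID defaults to 5.5 mmol/mol (0.5%); 5 mmol/mol is
a common display alternative and both are supported rather than adjudicated.

`expected_matrix_normal()` is the analytic companion: two conditionally
independent $N(\mu, \mathrm{cv}\,\mu)$ draws mixed over a discrete grid of
true means, each draw conditioned on lying inside the outer bin edges
(mirroring range cleaning), with per-bin MCID integrals evaluated by
32-node Gauss–Legendre quadrature. The tests verify it against Monte-Carlo
oracles and verify the empirical builder converges to it on a 50,000-patient
synthetic cohort, comparing rows with at least 2500 pairs so that the
binomial sampling error of the empirical cells themselves sits inside the
0.02 sup-norm tolerance (sparse tail rows cannot beat their own noise).

## Clinical decision probabilities

Under the normal measurement model a single result differs from the true
mean $\mu$ by at least the MCID $d$ with probability
$2\,(1-\Phi(d/(\mathrm{cv}\,\mu)))$ — `prob_beyond_mcid()`. For a true mean
of 58 mmol/mol and CV 0.182 this is 0.60: more likely than not, a lone
result is clinically misleading. `misclassification_prob()` gives the
probability that a measured result falls on the wrong side of a decision
threshold. `simulate_ci_width()` is the design-precision check behind the
100-participant floor: at CV 20%, 100 participants × 4 observations give a
median total 95% CV-interval width of about 3 percentage points across 500
replicates, comfortably below the 10-point (±5%) planning bound.

## Problem sizes and reproducibility

The test suite exercises recovery at 2000 patients × 10 visits for CVs of
0.05, 0.10 and 0.20; interval coverage over 500 replicated cohorts;
transition-matrix convergence at 50,000 patients; and Monte-Carlo oracles at
$10^6$–$10^7$ draws — sizes at which Monte-Carlo error is well inside each
stated tolerance while the whole suite runs in well under a minute. All
generator randomness flows from the config seed (identical seed and config
give byte-identical cohorts), and `run_pipeline()` derives per-stage seeds
from a single root seed so every stage is individually reproducible.

## Known limitations

* CV~T~ pools analytical, pre-analytical and biological variation; no
  decomposition is attempted.
* The chi-square interval is mildly anti-conservative (≈94% at large
  designs) and assumes homoscedastic normal within-patient noise.
* The constant-CV noise model makes the pooled within-SD slightly larger
  than $\mathrm{cv} \times$ mean when between-patient spread is wide.
* Covariate-adjusted (regression) CV estimation and time-gap dependence of
  repeat results are out of scope.
* The generator's covariate distributions are marginal only — no
  correlation between, say, BMI and diabetic status beyond stratum-specific
  laws.
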