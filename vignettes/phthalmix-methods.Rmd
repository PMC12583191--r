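---
title: "Models and methods in phthalmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phthalmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phthalmix)
```

`phthalmix` implements a pooled multi-cohort analysis of early-life urinary
phthalate and bisphenol exposure and repeated childhood allergy outcomes.
This vignette is the package's own account of the models it fits, the
defaults it ships, the parts of the design that were genuinely open and how
they were settled, and what the synthetic-data tests do and do not
demonstrate.

## The exposure pre-processing chain

Urinary biomarker concentrations are not comparable across spot samples
without correcting for urine dilution. Two standard corrections are
implemented, selected per cohort profile: the Levine–Fahey specific-gravity
rescaling `E0 * (Sg_median - 1)/(Sg0 - 1)` and the Boeniger creatinine
rescaling `E0 * Cr_median/Cr0`, with the medians taken over the study sample
being standardized. Specific gravity must exceed 1 for the correction to be
defined; imputed specific-gravity values are floored at 1.001 for the same
reason.

Measurements below the limit of detection (LOD) are handled on the raw assay
scale, before dilution correction — the LOD is a property of the assay, so
substitution and imputation refer to that scale. Two strategies are
available:

* **LOD/√2 substitution**, the standard choice for phthalates, whose
  detection rates are high (inclusion requires > 50% detection);
* **left-censored lognormal multiple imputation** for bisphenols (included
  above 10% detection): a lognormal is fitted per analyte by maximum
  likelihood with censored observations contributing `F(LOD)` to the
  likelihood (via `fitdistrplus::fitdistcens`), and each censored value is
  drawn from the fitted distribution truncated to `(0, LOD)`, independently
  in each of `m = 5` imputed datasets.

Detected values are never altered by either method; this is asserted by the
test suite.

Time-of-day adjustment uses the residual method: log concentration is
regressed on linear and quadratic clock-time terms and replaced by residual
plus grand mean. The quadratic term is a deliberately cheap description of
diurnal curvature; the functional form is configurable in the sense that the
adjustment is a separate, skippable stage. Batch adjustment equalizes batch
means on the log scale (mean-centering plus grand mean). The batch
"weighting" procedure used by one contributing cohort is not reproducible
from public descriptions, so this simplest mean-equalizing adjustment stands
in for it and is labelled as such. Whether time-of-day adjustment precedes
or follows dilution correction is likewise not documented; the chain applies
dilution correction first and then the log-scale adjustments, and each stage
is independently switchable per cohort profile (several cohorts applied no
time-of-day adjustment at all).

## Estimated daily intake

Parent-compound daily intakes are back-calculated from metabolite
concentrations:

$$EDI = \frac{C_{adj}\, UV\, MW_{diester}}{FUE\, W\, MW_{metabolite}}
\quad \left[\mu g / kg / day\right]$$

* `UV` defaults to 1.6 L/day during pregnancy; postnatally `UV/W` comes from
  a piecewise-constant normative table over age bands (0–1, 1–3, 3–6 years:
  0.040, 0.030, 0.025 L/kg/day), shipped as replaceable configuration.
* `W`, maternal weight at sampling, is pre-pregnancy weight plus the
  cumulative gestational gain recommended by the Institute of Medicine,
  encoded as a first-trimester total of 2 kg accrued linearly to week 13
  plus a BMI-category weekly rate (0.51/0.42/0.28/0.22 kg/week for
  underweight/normal/overweight/obese), the guideline midpoints.
* Molecular weights follow the molecular formulas; fractional urinary
  excretion values are the ones in common use in the biomonitoring
  literature. Both live in a versioned TSV (`analyte_registry()`) that users
  can override, because published analyses cite literature constants rather
  than printing them.

DEHP aggregates its metabolites as a molar sum converted back to parent mass
and divided by the *summed* FUE of the metabolites actually present. This
convention makes metabolite subsets (panels lacking MEHP, or MECPP) behave
consistently: dropping a metabolite removes both its molar contribution and
its share of expected excretion. No authoritative subset-specific FUE values
exist, so the summed-FUE rule is the package's explicit choice, and the
DEHP-restriction sensitivity analysis (`compare_dehp_restriction()`)
quantifies its consequences. DBP is the arithmetic sum of the DiBP and DnBP
intakes. MCPP, a non-specific metabolite of several high-molecular-weight
phthalates, is analysed as a urinary concentration, never as an intake; the
full standardization chain is applied to it uniformly, since nothing in the
source analyses distinguishes its treatment.

Prenatal exposures are averaged per subject on the natural scale and then
log2-transformed. Averaging log values instead would estimate the effect of
the geometric-mean exposure — a different estimand. Trimester-stratified
analyses bin samples at <14, 14–27 and ≥28 gestational weeks (the obstetric
convention; the boundaries are arguments).

## Outcome alignment

Outcomes are harmonized to four binary conditions (asthma, wheeze, eczema,
rhinitis) assessed between birth and five years. Cohort-specific codings map
through explicit tables; clinician-assessed "possible" diagnoses map to
non-case, keeping only definite diagnoses as cases.

The prenatal analysis regresses each subject's repeated outcome assessments
on their single averaged exposure. The postnatal analysis is lagged: the
exposure measured at age *t* is paired with the outcomes assessed in the
half-open window *(t, t']* up to the next exposure (the last window extends
to age five). Two conventions here were genuinely open:

* **Boundary**: the window is half-open on the left, so an assessment at
  exactly the sampling age is never explained by that sample — strict
  temporal precedence holds for every analysis row and is asserted by a
  property test.
* **Aggregation**: when several assessments fall inside one window the
  window is a case if *any* assessment is positive, matching the
  "ever had X" phrasing of the underlying questionnaires; the window's
  age-at-assessment covariate is the mean assessment age.

## Single-compound models

The inferential engine is a log-link Poisson marginal model estimated by
generalized estimating equations with an exchangeable working correlation,
clustered by child, with robust (sandwich) covariance. For binary outcomes
the log link makes `exp(beta)` a risk ratio, and a log2-transformed exposure
makes it a risk ratio per doubling. The implementation is written in the
package (no GEE dependency): the exchangeable inverse correlation has the
closed form `c1*I + c2*J`, so every cluster sum reduces to `rowsum()` calls
and fitting scales linearly in rows.

Numerical choices:

* convergence when the relative coefficient change falls below `1e-8`, with
  a 200-iteration cap; the exchangeable correlation and dispersion are
  re-estimated by moment updates each step, with the correlation clamped to
  `[0, 0.95]`;
* clusters of size one make the working correlation vacuous; the fit then
  equals an independence Poisson GLM with HC0-type robust errors to 1e-6
  (a test asserts this against `glm` + `sandwich::vcovCL`);
* diverging coefficients (|beta| > 50, or linear predictors above 30) raise
  a distinct error, since small strata with rare outcomes can separate;
* confidence intervals are Wald on the log scale with z = 1.96; no
  multiple-testing correction is applied anywhere, matching the
  signal-detection stance of the analyses the package supports.

Dose–response curves replace the linear exposure term with a restricted
cubic spline (truncated-power basis, linear beyond the boundary knots) with
three knots at the exposure's 10th/50th/90th percentiles; non-linearity is
tested by a robust Wald test on the non-linear coefficients. Curves are
normalized to relative risk 1 at the median exposure with covariates held at
reference values (means for continuous, first level for categorical), which
cancel exactly in the ratio. Sex effect-measure modification uses an
exposure-by-sex interaction; stratum-specific risk ratios are contrasts of
the interaction model (with only the exposure interacted, these coincide
with covariate-conditional marginal contrasts), and the interaction p-value
is the robust Wald test.

## Mixture models

Quantile g-computation quantizes each compound to scores `0..q-1` by average
ranks mapped through `floor(rank * q/(n+1))` — a deterministic tie rule that
sends tied values to one bin and makes scores invariant to monotone
transforms. The underlying log-link risk model includes all quantized
compounds plus covariates; the mixture effect is `psi = sum(beta_j)`, the
log risk ratio of raising every exposure one quantile simultaneously, and
per-compound weights are coefficients normalized within their sign
partition (each partition's absolute weights sum to 1, asserted to 1e-10).

Repeated measures are handled by subject-clustered bootstrap: subjects are
resampled with replacement, the underlying model is refitted per replicate,
and the CI is the percentile interval of `psi` over 1000 replicates by
default. The source analyses describe "subjects as random intercepts" with
bootstrap CIs; this package targets the marginal (population-averaged)
effect, consistent with its GEE single-compound analyses, and the
percentile bootstrap is agnostic to that choice. Resampling is at the
subject level — the correct unit under repeated measures — though the
alternative was unstated in the source. Replicates that fail to converge
are dropped and counted; more than 10% dropped is a hard error.

Non-linear mixture curves refit at q = 20 under linear, quadratic, cubic and
restricted-cubic-spline score expansions, select the smallest AIC from the
underlying likelihood, and report the g-computation curve: predicted mean
risk with all compounds set to joint quantile *s*, averaged over the
observed covariate distribution, relative to quantile 0. Sex interaction
uses score-by-sex terms for every compound; per-sex `psi` values come from
the coefficient sums, and the interaction p-value is the two-sided bootstrap
p of the `psi` difference.

Default compound sets follow the measurement reality of the pooled cohorts:
the prenatal mixture excludes DMP, BPS and BPF and the postnatal mixture
excludes BPA (insufficient coverage); subjects lacking any mixture compound
are excluded before quantization.

## Sensitivity suite

* **E-values**: `E = RR + sqrt(RR(RR-1))` for RR ≥ 1, applied to the
  reciprocal for protective estimates; the CI-bound E-value uses the limit
  nearer the null and is 1 when the interval crosses 1. Reported to two
  decimals.
* **Random-effects meta-analysis** over cohort-stratified estimates:
  τ² by REML (via `metafor`), inverse-variance pooling with weights
  `1/(se² + τ²)`, and I² computed from Cochran's Q as
  `max(0, (Q - df)/Q) * 100`.
* **Stabilized selection weights**: `P(S=1)/P(S=1|X)` from a logistic
  model, truncated at the 1st/99th percentiles by default (truncation is a
  variance-control choice and can be disabled); weighted GEE fits accept the
  weights directly. Perfectly predictive covariates raise an error.
* **Chained-equations imputation** of missing covariates: per-variable
  conditional draws (Bayesian linear regression for continuous, logistic
  for binary, multinomial for multi-level factors), five datasets and
  twenty sweeps by default, pooled by Rubin's rules on the log-RR scale.
  With nothing missing the pooled result equals the complete-data fit
  exactly.
* **DEHP metabolite restriction** re-derives the molar sum on the subset
  measured everywhere and reports full versus restricted risk ratios side
  by side.

## The synthetic generator: what it emulates, and what it does not

`cohort_spec()` defaults encode the pooled study conditions the package
targets: right-skewed exposures as multivariate lognormals parameterized by
geometric means and GSDs (e.g. prenatal DEHP GM 3.85 µg/kg/day, GSD 3.78),
outcome prevalences per assessment (prenatal asthma 14.6%, postnatal wheeze
59.8%, ...), covariate marginals (51% male, maternal age 30.4 ± 5.6 years,
...), urine samples at 16/26/36 gestational weeks or 1/2/3 years of age,
and MCAR covariate missingness. Exposure correlations across compounds
default to an exchangeable 0.3 on the log scale — a typical magnitude for
co-excreted metabolites; the source analyses plot but do not print their
correlation matrices, so the matrix is an input, not an asserted value.

Within-subject structure: repeated urine samples share a subject-level
log-scale component (60% of variance by default, a realistic biomarker
reproducibility); repeated outcomes share a lognormal frailty with mean 1
(log-sd 0.3 by default) multiplying the per-assessment risk, inducing the
moderate exchangeable-type dependence the GEE is designed for. GEE targets
the marginal model whatever the dependence mechanism, which is why a frailty
was chosen for the generator. Risks implied by the log link can exceed 1
for extreme draws; they are truncated at 0.99 with a warning. With
high-prevalence outcomes (postnatal wheeze, eczema) this truncation
attenuates recovered risk ratios by well under one percentage point at the
shipped frailty level — visible in the recovery studies as geometric-mean
estimates of about 1.081 against a generating 1.09 — and is accepted as the
price of keeping the generator total.

Effects are injected on the per-doubling scale
(`risk = baseline * RR^(log2 x - log2 GM)` per compound) or, for mixture
studies, on the quantile scale: the joint per-quantile log risk ratio is
split equally across compounds and applied to population-quantile scores,
centred to preserve the baseline prevalence. An optional confounding switch
makes one covariate shift exposure and outcome risk simultaneously, to
exercise adjustment and the selection-bias corrections.

What the generator does **not** emulate: cohort recruitment and attrition,
outcome misclassification, measurement error in covariates,
missing-not-at-random mechanisms, non-lognormal exposure tails, or
between-cohort protocol heterogeneity beyond per-cohort parameter sets.
Passing recovery tests therefore show that the estimators are correct for
data satisfying their assumptions at realistic parameter values — not that
those assumptions hold in any real cohort.

## Problem sizes and test design

The test suite is the package's specification in executable form. Sizes were
chosen to make Monte-Carlo tolerances meaningful while keeping the suite
brisk: generator calibration at n = 10,000 (3 standard-error tolerance);
single-compound recovery at 2,900 subjects (prenatal) and 1,700 (lagged
postnatal) over 50 replicates with nominal-95% CI coverage required at or
above 90%; mixture recovery at 1,586 subjects, quartile scores and 200
bootstrap replicates over 50 study replicates; spline-test calibration over
30 replicates of a linear truth. Structural identities (psi = sum of
coefficients, weight normalization, GLM equivalence at cluster size one,
dilution and substitution arithmetic, Rubin no-op) are asserted at
tolerances of 1e-6 to 1e-12.

## Known limitations

* The batch adjustment is a mean-equalizer, not a reproduction of any
  cohort's proprietary weighting scheme.
* The censored-lognormal imputer assumes a lognormal exposure; heavy
  departures below the LOD are invisible by construction.
* Subset-FUE handling for DEHP uses summed constituent FUEs; if the true
  excretion fractions are not additive across metabolites, restricted and
  full aggregations differ by more than a constant factor.
* `fit_qgcomp`'s point estimate comes from an independence working model;
  clustering enters through the bootstrap. A conditional (true random
  intercept) variant is out of scope.
* The E-value is a bias-magnitude bound, not a test; it inherits all
  assumptions of the risk-ratio scale it is computed on.
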