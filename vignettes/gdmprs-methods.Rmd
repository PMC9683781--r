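---
title: "Methods: simulating and analysing a T2D polygenic score against gestational diabetes traits"
author: "gdmprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a T2D polygenic score against gestational diabetes traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdmprs)
```

## The scientific setting

Gestational diabetes mellitus (GDM) — hyperglycemia first recognized in
pregnancy — shares most of its genetic architecture with type 2 diabetes
(T2D). A T2D polygenic risk score (PRS), a weighted sum of risk-allele
dosages, can therefore be tested against GDM and the underlying oral glucose
tolerance test (OGTT) traits: fasting plasma glucose (FPG), post-load glucose
at 1 and 2 hours, and the area under the glucose-time curve (AUCg). `gdmprs`
implements that whole analysis chain for a two-study design of unequal size
(one smaller cohort with a 3-point OGTT and diet data, one larger with a
2-point OGTT and no diet data): phenotype derivation, PRS construction and
evaluation, association and interaction models, two-study inverse-variance
meta-analysis, model-based population attributable fractions (PAF), a
screening-performance converter, and Monte-Carlo interaction power.

Because individual-level cohort data of this kind are access-restricted, the
package ships a synthetic-data generator as a first-class, tested module. All
statistical machinery is exercised end to end on generated data whose
parameters default to published pooled effect estimates, so that parameter
recovery is a meaningful test.

## The synthetic cohort generator

`simulate_cohort()` draws, per mother: age (normal, truncated to 18–43),
height, BMI (weight is derived as BMI × height²), parity (Poisson with mean
increasing in age, inducing the expected positive age–parity correlation),
an education category under the study's coding scheme, country of birth
(South-Asian countries with study-specific mixture), years in the
recruitment country, parental diabetes history, and — in the diet-collecting
study — six food-frequency intakes (log-normal, with the fried/fast-food
intake drifting upward with BMI so that poor diet and adiposity are
associated).

Glucose traits are linear in the design:

fpg = a_f + b' x + e,  with analogous equations for 1 h and 2 h glucose,

where x = (PRS_z, age, BMI, parental history, born in South Asia, parity,
education level, low diet quality) and e is independent Gaussian noise. The
coefficient defaults (`default_trait_coefficients()`) are the pooled
multivariable estimates for FPG and 2-hour glucose (e.g. 0.085 mmol/L per SD
of PRS on FPG, 0.207 on 2-hour glucose); since no coefficient set is
published for the 1-hour trait (it exists in only one cohort), its row is set
once to the midpoint of the FPG and 2-hour rows. Intercepts and residual SDs
(3.30/5.49/2.50 and 0.45/1.70/1.45 mmol/L) were chosen once so that the
marginal trait means and SDs approximate the published descriptive table and
the IADPSG GDM prevalence lands in the reported 11–25% band; they are not
revisited.

Key design decisions:

* **GDM is never simulated directly.** It must emerge from threshold
  classification of the simulated glucose values downstream; this is what
  makes prevalence monotone in the glucose intercepts, a tested invariant.
* **One genotype per mother.** Mothers with multiple pregnancies (15% by
  default, 2–3 rows) share a genotype and hence a PRS; OGTT values are drawn
  independently per pregnancy.
* **Missingness is completely at random**, applied last, field by field,
  at small per-field rates (1–3%). Self-reported GDM is generated for 60% of
  pregnancies with 90% agreement with the OGTT truth, exercising the
  fallback path in the classifier.
* **No linkage disequilibrium and no relatedness.** Variants are independent
  binomial draws in Hardy–Weinberg proportions. This is deliberate: it keeps
  the scoring and PCA stages analytically transparent, but it means passing
  tests say nothing about LD-aware score construction or kinship-adjusted
  PCA on real data.
* Residuals of the three glucose traits are independent given the design.
  Real OGTT values are correlated within a woman beyond what shared
  covariates induce; marginal analyses are unaffected, but the generator
  should not be used to study joint trait distributions.

`generate_weights()` designates `floor(n × prop_nonzero)` variants as causal
with normal weights and source-GWAS p-values log-uniform below 1.4e-3;
null variants carry zero weight and uniform p-values. This mirrors the
situation in which p-value thresholding can in principle recover the causal
set.

## Phenotype derivation

* **GDM classification** (`classify_gdm()`): IADPSG — GDM iff FPG ≥ 5.1, or
  1-hour ≥ 10.8 (when measured), or 2-hour ≥ 8.5 mmol/L; the South-Asian-
  specific secondary definition — FPG ≥ 5.2 or 2-hour ≥ 7.2. All thresholds
  inclusive. The 1-hour IADPSG cutoff is implemented as 10.8 mmol/L, the
  value used by the studies this package models, although 10.0 appears
  elsewhere in consensus documents. A pregnancy is called GDM whenever any
  measured value crosses a threshold; it is called non-GDM only when fasting
  and 2-hour values are both present (so the rule could actually be ruled
  out); otherwise the self-report/chart value is used, and failing that the
  status is missing — not an error.
* **AUC glucose** (`auc_glucose()`): trapezoidal rule over the available
  timepoints (3-point and 2-point formulas). AUCg is log-transformed,
  winsorized, and standardized within study before modelling
  (`log_winsorize_standardize()`). The winsorization limits are not
  prescribed anywhere, so the common 1st/99th percentile convention is the
  default and configurable; it only affects extreme tails.
* **Diet-quality score** (`diet_quality()`): one point per favourable food
  group at or above the study median, one per unfavourable group strictly
  below it; 0–6 points; Low ≤ 2, Medium 3–4, High 5–6. A score of 0 is not
  assigned by the published category labels ("1 or 2" is Low); it is treated
  as Low, the monotone extension. Equality at the median is decisive: ≥
  passes for favourable groups, < fails for unfavourable ones, so an
  all-median woman scores exactly 4.
* **Education**: five ordered levels in the START-like scheme, four in the
  BiB-like scheme; unclassifiable foreign degrees map to missing. The
  post-secondary binary is level ≥ 3 (five-level scheme) and level 4
  (four-level scheme); the cutoffs are a configuration choice recorded here
  because no explicit cutoff is published.
* **Index pregnancy** (`select_index_pregnancy()`): drop pregnancies with
  missing GDM; prefer covariate-complete pregnancies, then fewest-missing;
  among survivors keep the latest pregnancy if all GDM-negative ("older
  controls") and the earliest GDM-positive otherwise ("younger cases"). A
  date tie between GDM-positive pregnancies keeps the first in input order —
  a deterministic tie-break the source rules leave open. Note the ordering
  of the completeness filter ahead of the case/control rule means a complete
  GDM-negative pregnancy can displace an incomplete GDM-positive one; the
  steps are applied exactly in the order stated.

## The PRS engine

Scoring is the plain weighted dosage sum over variants passing a source-GWAS
p-value threshold, with allele harmonization (flip when the weight's effect
allele equals the genotype's other allele, drop with a warning otherwise)
and mean-dosage imputation of missing genotypes.

**LD-aware shrinkage is intentionally not implemented.** The score variant
is selected by a grid search over 17 p-value cutoffs log-spaced from 5e-8
to 1, maximizing the validation AUC on a 70/30 split stratified by study.
In the absence of LD (true of the generator by construction), posterior
shrinkage of independent-variant weights is close to a uniform rescaling
within a p-value stratum, and AUC-based selection is invariant to any
strictly monotone transformation of the score — an invariant the test suite
asserts. A heritability grid dimension would therefore be inert here and is
not part of the implementation.

Conventions pinned by tests: standardization uses the sample SD (n − 1);
tertile boundaries assign ties to the lower tertile; the AUC is the
Mann–Whitney rank statistic with ties counted ½.

`genotype_pca()` standardizes each variant by its binomial moments
(center 2p, scale sqrt(2p(1−p))) and takes the top-k singular vectors. This
is ordinary genotype PCA; kinship-adjusted PCA is unnecessary for the
generator's unrelated individuals and is out of scope for real data.

## Association models

Linear models use ordinary least squares with classical SEs; logistic models
use IRLS (convergence 1e-8, 25 iterations) with observed-information SEs;
both report Wald 95% CIs (z = 1.959964; the CI is always estimate ±
1.96·SE up to that constant, a self-consistency the tests assert).
Complete-case analysis throughout, with the used n reported. The descriptive
table uses the pooled-variance Student t by default (a Welch option exists)
and Pearson chi-squared without continuity correction. Interaction models
add a single product term. No multiple-testing correction is applied —
interaction p-values are reported nominally, matching the modelled analyses.
Parity enters models as a continuous count (configurable); education as a
single ordinal term.

## Two-study meta-analysis

`pool_fixed()` is inverse-variance fixed-effect pooling; heterogeneity is
Cochran's Q with its chi-squared p-value and I² = max(0, (Q − df)/Q)·100.
The fixed-effect model is the default because it reproduces published pooled
columns exactly (including a row with I² = 90, where a random-effects model
would not); a DerSimonian–Laird option (`pool_random()`) is provided.
Betas pool on the identity scale; odds ratios on the log scale
(`pool_or()`). Attributable fractions pool on the identity scale: published
pooled AF rows are reproduced by identity-scale pooling, and AFs can be
negative, which a log-scale pool could not represent. With two studies and
no moderators, residual heterogeneity coincides with Cochran's Q, which is
what is computed. `se_from_ci()` recovers SEs from printed CIs using
z = 1.959964; the difference from 1.96 is below any reporting precision.

## Population attributable fractions

`af_model_based()` implements model-based standardization:
AF = 1 − Σ p̂ᵢ(exposure←reference) / Σ Yᵢ, the fitted expected case count
with the exposure removed (confounders at observed values) over the observed
case count. On a saturated unadjusted model this equals the 2×2 closed form
AF = P(E|D)(RR−1)/RR to numerical precision — a tested oracle. The default
uncertainty is a seeded nonparametric bootstrap (B = 500, percentile CI);
a delta-method variance conditional on the observed cases is available as an
approximate alternative. Exposure codings follow the published contrasts:
age <29 / 29–31 / ≥32 (reference <29, with a binary ≥29 variant available),
BMI ≥ 23 (the South-Asian obesity cutoff, inclusive), PRS tertile 3 versus
tertiles 1+2, parity ≥ 1, study-scheme post-secondary education, parental
history, born in South Asia, and low diet quality. Summed PAFs are plain
sums of point estimates, flagged as an approximation with no independence
claim.

## The screening converter

`detection_rate()` converts a top-tertile odds ratio into screening
performance under an equal-variance Gaussian score model: standard normal in
unaffected women, mean d in affected women. With exposed fraction f (exactly
1/3 for a tertile contrast), the cutoff is c = Φ⁻¹(1−f); the case
probability above the cutoff solves OR = [p/(1−p)]·[(1−f)/f]; then
d = c − Φ⁻¹(1−p) and DR = 1 − Φ(Φ⁻¹(1−FPR) − d). The equal-variance normal
model is chosen because it reproduces the published 10% detection rate at 5%
false-positive rate from the pooled tertile counts; the <1% distortion of
the control-group tertile fraction induced by disease prevalence is ignored.
A simulation round-trip test (n = 5×10⁵ normal scores) confirms the implied
d reproduces the input OR within sampling error.

## Interaction power

`interaction_power_mc()` draws correlated standard-normal predictors,
generates the outcome from b₁x₁ + b₂x₂ + b₃x₁x₂ (Gaussian noise or a
logistic link around a configured prevalence), fits the interaction model
and counts rejections at α. Measurement reliabilities are fixed at 1 — the
published power analyses depend on unprinted nuisance parameters, so the
implementation targets the qualitative regimes: near-α rejection under the
null (tested against 3 MC SEs), agreement with the noncentral-t closed form
for linear models, power below 20% at the smaller study's size for a
per-unit interaction OR of 0.98, and power above 80% for a strong
standardized interaction.

## Numerical choices and problem sizes

Degenerate inputs raise errors rather than silently propagating: constant
scores cannot be standardized, zero-variance winsorized values cannot be
scaled, empty outcome classes have no AUC, separated logistic fits are
reported as non-convergence, zero cells have no odds ratio. The test suite
runs the generator at up to 20,000 mothers for the main parameter-recovery
check, 1,000 for interaction recovery, 100 replicates × B = 500 bootstrap
for PAF CI coverage, and 2,000 Monte-Carlo simulations for the type-I power
calibration — sizes chosen to keep Monte-Carlo error comfortably inside the
asserted tolerances.

## Limitations

The generator's covariate dependence structure is limited (age–parity and
BMI–diet only); there is no LD, admixture, relatedness, or informative
missingness; glucose residuals are independent across OGTT timepoints; and
the self-report mechanism is a fixed-accuracy coin flip. Tests passing on
this generator validate the statistical machinery and its contracts, not the
behaviour of PRS construction on real, linked, structured genotype data.
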