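---
title: "Accounting for socio-economic inequality in excess weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for socio-economic inequality in excess weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthineq)
library(dplyr)
```

## The problem

Excess weight (BMI ≥ 25 kg/m²) is not distributed evenly across society: in
England and most developed economies it falls disproportionately on people
living in deprivation. Quantifying *how much* of the burden is concentrated
among the deprived — and *which factors* account for that concentration — is
the prerequisite for targeting public-health policy. This package implements
a complete accounting pipeline for that question on individual-level survey
records: survey-weight construction, rank-based concentration indices with
inference, and a Shapley decomposition of explained inequality, together
with a synthetic-data generator that makes the whole pipeline testable
against analytic ground truth.

## The data model

One row per adult: BMI (kg/m², possibly missing), nine English regions,
seven age bands, gender, five ethnic groups, a limiting-illness flag,
marital status, urbanicity, a design weight and a response indicator, plus
three *deprivation-ordered* scales with higher codes meaning more deprived —
IMD quintile (1–5), NS-SEC occupational class (1–6) and NVQ-based
educational qualification (1–8). `survey_codebook()` declares the levels;
`validate_survey()` enforces them. BMI is classified with half-open
intervals `[x, y)`: underweight (< 18.5), healthy (18.5–<25), overweight
(25–<30), obesity I (30–<35), II (35–<40), III (≥ 40), and the three nested
flags are excess weight (≥ 25), obesity (≥ 30) and morbid obesity (≥ 35).
Underweight records keep all flags 0 and stay in every denominator.

## Weighting

BMI is typically missing for a non-trivial share of respondents (the
generator's default emulates 18.6%). Treating the missingness as
missing-at-random given observed covariates, `fit_response_propensity()`
fits a main-effects logistic model of response and `compute_ipw()` inverts
the fitted propensities (floored at 0.02) so responders stand in for the
non-responders they resemble. `rake()` then aligns the weighted sample
margins with known population quotas by classical iterative proportional
fitting (tolerance 1e-6 on margin proportions, at most 50 cycles, weight
total preserved across cycles), and `combine_weights()` multiplies design,
IPW and raking factors, caps the product at 5× its median and normalises it
to mean 1 over responders. The floor and cap are not dictated by any data
source; they are conventional variance-inflation guards and both are
configurable. Raking with a single targeted dimension reduces to exact
post-stratification in one pass.

## Concentration indices

For outcome $y \in [a, b]$ with weighted mean $\mu$ and weighted fractional
rank $r$ over a deprivation scale, the Erreygers corrected concentration
index is

$$\mathrm{CCI} \;=\; \frac{4\mu}{b-a}\cdot\frac{2\,\mathrm{cov}_w(y, r)}{\mu}
\;=\; \frac{8\,\mathrm{cov}_w(y, r)}{b-a},$$

with range $[-1, 1]$. The simplified form avoids dividing by $\mu$, so a
zero-prevalence stratum still evaluates (to 0). The Wagstaff alternative
multiplies the standard index $2\,\mathrm{cov}_w(y,r)/\mu$ by
$(b-a)\mu/\big((b-\mu)(\mu-a)\big)$; for a binary outcome the two satisfy
$E = 4\mu(1-\mu)\,W$ exactly. Ranks are weighted mid-ranks per category
(ties always share the mid-rank; no jittering), computed most-deprived
first, so the weighted mean rank is exactly 0.5 and **a negative index
means the outcome is concentrated among the most deprived**. We fix this
direction because it is the convention under which published national
estimates of pro-deprived concentration in excess weight are negative;
reversing the scale flips the sign exactly. Binary outcomes use bounds
(0, 1); for continuous BMI no canonical bounds exist, so they are
configurable with default (12, 60) kg/m² chosen to cover the plausible
adult range — index values for continuous BMI therefore depend on that
choice and are only comparable under equal bounds.

Inference is a nonparametric bootstrap by default (records resampled with
their weights, ranks recomputed per replicate, SE = replicate SD, two-sided
normal-approximation p), with a delta-method (influence-function) SE as the
fast alternative; the two agree within ~15% at moderate samples. The
bootstrap is the default because it is agnostic to ties and weight
structure. Ranks are recomputed within each analysed stratum by default;
`rank_within_stratum = FALSE` carries nationally anchored category ranks
into regional or gender strata instead (in that mode the in-stratum mean
rank is no longer 0.5 by construction).

## Shapley decomposition of the dissimilarity index

Explained inequality in a binary outcome is summarised by the
dissimilarity index of model-fitted probabilities,

$$DI \;=\; \frac{\sum_i w_i\,|p_i - \bar p|}{2\,\bar p \sum_i w_i},$$

where $p_i$ comes from a weighted logistic main-effects model on a factor
set and $\bar p$ is the weighted prevalence. Neither the outcome-model
family nor the DI formula is canonical in the applied literature, so both
choices are declared here prominently: weighted logistic regression and the
classical (weighted) dissimilarity index; published contribution
percentages depend on them. The Shapley value of factor $k$ averages its
marginal DI contribution over all elimination orders, computed exactly by
enumerating all $2^m$ factor subsets with one memoised model fit per
subset, with $DI(\varnothing) = 0$ so the efficiency identity
$\sum_k \phi_k = DI(\text{full})$ holds to machine precision. Per-factor
p-values come from a record bootstrap (default 200 replicates) with a
normal-approximation test of $\phi_k \ne 0$. Separation in any subset fit
falls back to a lightly ridge-penalised logistic fit (penalty $10^{-4}$)
with a warning. The specification ladder mirrors a forward model-building
sequence — intrinsic characteristics (region, age, gender, ethnicity) plus
the deprivation scale under study; then personal circumstances (limiting
illness, marital status, urbanicity); then all three deprivation scales
jointly — and reports DI, contributions and BIC ($k\ln n - 2\ell$) per
step.

## The synthetic generator: what it emulates, and what it does not

`synthetic_config()` defaults define the study conditions the package is
validated under, emulating the structure of the 2019 Health Survey for
England wave: 6,387 adults with regional sample shares matching the
published per-region counts; marginal distributions for age, gender,
ethnicity, education, occupation and IMD taken from the published
descriptive table; an additive BMI model with Gaussian residual (SD 5.5
kg/m²) whose intercept (24.9 kg/m²) was solved from the chosen gradients to
give a mean of ≈ 27.9 kg/m² and excess-weight prevalence ≈ 0.68; monotone
deprivation gradients (+0.4 kg/m² per IMD quintile step, +0.3 per education
level, +0.25 per occupation class, +1.6 for limiting illness); a MAR
missingness logit on age and illness whose intercept (−1.699) was solved
analytically for an 18.6% expected missing fraction; and mild per-region
and per-occupation quota multipliers that raking to the true margins
corrects. BMI is floored at 12 kg/m² (measurement-scale censoring).

The survey does not publish its covariate joint distribution, so
dependence between the three deprivation scales is a stand-in: a one-factor
Gaussian copula with equicorrelation 0.3 (latent
$Z_d = \sqrt{\rho}\,U + \sqrt{1-\rho}\,\varepsilon_d$). The one-factor form
was chosen because the implied joint cell probabilities then reduce to a
one-dimensional Gauss–Hermite quadrature (64 nodes) over the shared factor,
which keeps `ground_truth()` a deterministic expectation rather than a
simulation: effect sums convolve across independent dimensions, the copula
triple contributes a 240-cell joint, threshold probabilities use the
Gaussian c.d.f. and the floor uses the censored-normal mean formula. The
optional `binary_gradient` mode draws the excess-weight flag directly from
a logistic model (with BMI pinned to flag-consistent values) so index
recovery can be tested against a logistic oracle as well.

What passing tests on this generator do **not** show: the generator has no
multistage PSU/postcode-sector design, no spatial autocorrelation, no
interactions in the BMI model, and its covariate dependence is the declared
copula, not the real joint distribution — so recovery results certify the
estimators under the stated model, not the sampling properties of any real
survey.

## Numerical choices and degenerate inputs

- IPF: tolerance 1e-6 on margin proportions, 50-cycle cap, error (carrying
  the last deviation) on non-convergence; empty targeted levels are errors
  naming the level.
- Constant outcome: Erreygers index is exactly 0; Wagstaff errors (mean on
  a bound). Degenerate bootstrap distributions error rather than return a
  zero SE.
- Probability-one missingness cells are errors; probability-zero cells
  leave the table unchanged.
- Strata with fewer than 100 responders (configurable) are skipped with a
  logged reason rather than estimated — regional survey cells can be small
  and bootstrap inference there is unstable.
- All randomness is seeded; a report regenerates bit-identically from
  (config, seed), and sub-stream seeds are derived deterministically from
  the master seed.

## Problem sizes used in validation

The packaged validation suite exercises: exact-formula and
concentration-curve-oracle checks at $n \le 12$ (full enumeration);
marginal recovery and zero-gradient null checks at $n$ = 20,000–50,000;
analytic-truth recovery at $n$ = 200,000; type-I-error calibration with 500
simulations of $n$ = 1,000 (bootstrap 200 replicates); MAR/IPW bias
correction over 200 replicates of $n$ = 2,000; and Shapley axiom checks up
to $m = 5$ factors against an all-orderings oracle plus a dummy-factor
check at $n$ = 20,000. These sizes give Monte-Carlo error comfortably below
the tested tolerances while keeping a full run at desk scale.

## Known limitations

- The published national estimates derive from restricted-access microdata;
  `reproduce_hse_analysis()` runs the identical pipeline on a user-supplied
  licensed extract but the package cannot ship or fetch it.
- The Wagstaff variant is undefined for zero- or full-prevalence strata.
- Shapley p-values assume approximate normality of replicate values; with
  very small strata or near-zero contributions they are conservative at
  best.
- The dissimilarity index is computed over *fitted* probabilities, so a
  richer specification mechanically tends to a larger DI; BIC is reported
  alongside to keep specification choice honest.

## A short run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 2019)
report <- run_analysis(analysis_config(cfg, strata = "national", seed = 2019))
tidy(report)
compare_variants(report)$sign_agreement
autoplot(report)
```
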