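# healthineq

Socio-economic inequality accounting for excess weight in survey data.

## What this is for

Excess weight (BMI ≥ 25 kg/m²) falls disproportionately on people living in
deprivation, and public-health analysts need two numbers before they can
target policy: *how concentrated* the burden is along a deprivation scale,
and *which factors account* for that concentration. `healthineq` is a
tidyverse-native R package that computes both from individual-level survey
records (one row per adult: BMI, region, age band, gender, ethnicity,
education, occupation, IMD quintile, limiting illness, marital status,
urbanicity, design weight, response indicator), handling the two survey
realities on the way — missing BMI measurements and sampling-quota
imbalance.

It is aimed at health-inequality and health-economics researchers working
with surveys shaped like the Health Survey for England (which is
restricted-access; the package ships a synthetic generator emulating its
2019 structure so everything is runnable and testable without a licence).

## The statistics at its core

**Erreygers corrected concentration index.** For outcome
*y* ∈ [*a*, *b*] with weighted mean μ and weighted fractional rank *r*
along the deprivation scale,

    CCI = (4μ / (b − a)) × (2 cov_w(y, r) / μ) = 8 cov_w(y, r) / (b − a)

ranging over [−1, 1]. Ranks are weighted mid-ranks per category, most
deprived first, so **negative = concentrated among the most deprived**.
The Wagstaff variant `2 cov_w(y,r) (b−a) / ((b−μ)(μ−a))` is provided as a
robustness check; for binary outcomes `Erreygers = 4μ(1−μ) × Wagstaff`
exactly. Standard errors come from a record bootstrap (default) or a
delta-method linearisation.

**Shapley decomposition of the dissimilarity index.** Explained inequality
`DI = Σ w|p_i − p̄| / (2 p̄ Σ w)` — with `p_i` from a weighted logistic model
— is split exactly across factors by averaging each factor's marginal
contribution over all elimination orders (2^m memoised subset fits;
efficiency holds to machine precision), with bootstrap p-values and a
BIC-reported three-step specification ladder.

**Weighting.** Inverse probability weighting from a logistic response
model corrects missing-at-random BMI non-response; raking (iterative
proportional fitting) aligns sample margins with population quotas; the
combined weight is capped and mean-normalised.

## Worked example

```r
library(healthineq)
library(dplyr)

cfg <- synthetic_config(n_individuals = 4000, seed = 2019)  # HSE-2019-like
tab <- impose_missingness(generate_population(cfg), cfg)
#> impose_missingness: 19.2% of records masked
tab <- validate_survey(tab)
tab <- add_analysis_weights(tab, margin_targets(cfg))
resp <- filter(tab, responded == 1)

concentration_index(resp, "excess_weight", "education",
                    weights = "combined_weight", reps = 500, seed = 1)
#> <cci_fit> erreygers index of excess_weight over education [all]
#>   -0.1198 (se 0.0187, p 1.6e-10, n 3232)
```

The index of −0.12 (bootstrap SE 0.019) says excess weight in this
population is significantly concentrated among the least educated: on the
Erreygers scale, where −1 would mean the entire burden sits on the most
deprived end, this is a moderate but unmistakable pro-deprived gradient.

```r
shapley_decompose(resp, c("imd_quintile", "gender", "age_group",
                          "limiting_illness"),
                  "excess_weight", weights = "combined_weight")
#> <shapley_decomp> outcome excess_weight, DI 0.0566, n 3232, BIC 4017.1
#> # A tibble: 4 × 4
#>   factor           shapley_value contrib_percent p_value
#>   <chr>                    <dbl>           <dbl>   <dbl>
#> 1 imd_quintile           0.0228            40.3       NA
#> 2 gender                 0.00436            7.71      NA
#> 3 age_group              0.0130            23.0       NA
#> 4 limiting_illness       0.0164            29.0       NA
```

Of the explained inequality (DI = 0.057), neighbourhood deprivation
accounts for 40%, limiting illness 29%, age 23% and gender 8%; the four
contributions sum to the DI exactly (Shapley efficiency). `run_analysis()`
wraps the whole pipeline — weighting, stratified indices (national, nine
regions, by gender), both index variants, the specification ladder — behind
one seeded, reproducible call; `autoplot()` draws forest plots of the
estimates, and `tidy()`/`glance()` return broom-style tables. A thin CLI
over the same functions lives at `inst/cli/healthineq.R`.

Analysts holding the restricted-access 2019 Health Survey for England
extract under licence can run the identical national/regional/gender
analysis on it with `reproduce_hse_analysis("<path>")` after recoding to
`survey_codebook()`'s schema.

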