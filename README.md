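# crcdiet

Linking food-frequency dietary patterns, untargeted plasma metabolite
profiles, and colorectal cancer (CRC) risk in individually matched
case–control pairs.

Nutritional epidemiology increasingly combines three layers of evidence:
self-reported diet (food-frequency questionnaires, FFQs), objective
molecular read-outs (untargeted LC–MS plasma metabolomics), and disease
outcomes from prospective cohorts. `crcdiet` implements the full analysis
chain connecting these layers for 1:1 matched case–control designs, together
with a seeded synthetic-cohort generator so that every stage can be verified
against known ground truth at desk scale. It is aimed at biostatisticians
and molecular epidemiologists who want a tested, reusable, and fully
reproducible version of this pipeline.

## The methods

**Data-driven dietary patterns.** FFQ intake frequencies (9-level ordinal
scale from "never" to "≥ 4 times per day") are factor-analyzed by a repeated
random half-split stability procedure: on one half, exploratory factor
analysis (maximum-likelihood factorization, oblimin rotation via gradient
projection) proposes, for each factor count *k* in a scanned range, factor
structures from foods with |loading| > 0.3; on the other half, confirmatory
factor analysis (ML, factor variances fixed at 1) re-estimates them and
yields fit indices (CFI, TLI, RMSEA, SRMR). Factors are matched across
half-split repeats — and across *k* within the plateau of similar CFA
fitness — by Tucker congruence

φ(x, y) = Σxᵢyᵢ / √(Σxᵢ² · Σyᵢ²),

and only constructs reproduced in **every** repeat become dietary patterns.
A final CFA on all participants yields regression-method factor scores.

**Hypothesis-driven components.** Food-group amounts (g/day) such as red
meat, processed meat, their union, and total alcohol; all exposures are
energy-adjusted by the energy-density method (per 1000 kcal).

**Risk models.** For 1:1 matched pairs, the conditional likelihood

ℓ(β) = Σ_pairs [ β′(x_case − x_control) − log(1 + exp(β′(x_case − x_control))) ]

is maximized (via `survival::clogit`), with exposures standardized so odds
ratios are per 1 SD, adjustment for BMI, smoking, physical activity,
education, total energy and categorized alcohol (sex-specific non-zero
median split), pair-wise deletion of incomplete pairs, and stratification by
sex and tumor site (proximal colon, distal colon, rectum).

**Diet–metabolome models.** Metabolite features are QC-filtered
(coefficient of variation ≤ 30 % among pooled study-QC injections) and
completed by iterative random-forest imputation. Each dietary exposure is
then modelled from the feature matrix by repeated double cross-validated
(rdCV) random-forest regression with recursive variable elimination by
importance; predictive performance is Q² = 1 − PRESS/TSS on out-of-fold
predictions. Models with Q² > 0.15 are tested by permutation (default
n = 50), and selected features are validated by covariate-adjusted partial
Spearman correlation.

**Triplot integration.** PCA on the diet-selected features; component
scores are associated with CRC risk (conditional logistic) and with every
dietary exposure (partial Spearman), producing the three-layer "triplot"
tables.

## Worked example

```r
library(crcdiet)

cfg <- sim_config(
  n_pairs = 750,
  planted_log_or = c(breakfast_food = log(0.8)),
  seed = 42)
sim  <- generate_cohort(cfg)

freq <- derive_exposures(sim$diet)$freq_level
pats <- stability_select(freq, k_range = 3:6, n_rep = 5, seed = 43)
print(pats)
#> pattern_set: 4 stable dietary pattern(s) ( 5 half-splits, k in 3..6 )
#>   pattern_1 [x16]: food_07, food_08, food_09, food_10, food_11, food_12
#>   pattern_2 [x16]: food_13, food_14, food_15, food_16, food_17, food_18
#>   pattern_3 [x16]: food_01, food_02, food_03, food_04, food_05, food_06
#>   pattern_4 [x11]: food_19, food_20, food_21, food_22, food_23, food_24

ex <- attr(sim$diet, "latent_scores")[, "breakfast_food"]
fit_clogit(sim$cohort, ex, exposure_name = "breakfast_food")
#>         exposure stratum n_pairs        or    ci_low   ci_high            p
#> 1 breakfast_food     all     750 0.7587999 0.6773951 0.8499874 1.868397e-06
#>         beta         se unstable
#> 1 -0.2760171 0.05789968    FALSE
```

The four stable patterns are exactly the four planted latent factors (six
foods each), each reproduced in all five half-splits (the `[xN]` counts
tally appearances across the plateau of scanned factor counts as well).
The odds ratio per 1 SD of the planted breakfast-food exposure,
0.76 (95 % CI 0.68–0.85), recovers the planted log(0.8) = −0.223 within
sampling error at 750 pairs.

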