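---
title: "Methods: dietary patterns, metabolite profiles and matched case-control risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary patterns, metabolite profiles and matched case-control risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crcdiet` implements an analysis chain for nested matched case–control
studies of diet and colorectal cancer (CRC) with untargeted plasma
metabolomics: dietary-pattern derivation from food-frequency questionnaire
(FFQ) data, conditional-logistic risk estimation, diet–metabolome
association by cross-validated random forests, and an integrative
principal-component "triplot". Because cohort data of this kind are
typically not shareable, the package ships a seeded synthetic-cohort
generator whose planted structure serves as ground truth for every stage.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic data do and do not establish.

## The synthetic cohort generator

`sim_config()` / `generate_cohort()` simulate `2 * n_pairs` participants in
individually matched 1:1 pairs. Matching variables (sex, sub-cohort label,
age) are drawn once per pair, so they are exactly equal within pairs, as in
a register-matched design.

*Diet.* Latent dietary factor scores are standard normal per participant.
Food propensities are `loadings %*% scores` plus independent normal noise
whose variance tops the propensity up to unit variance (floored at 0.1), so
each food behaves like a unit-variance indicator in a common-factor model.
Propensities are discretized to the 9-level FFQ frequency scale by fixed
standard-normal quantile cut-points (cumulative probabilities 0.15, 0.35,
0.55, 0.70, 0.82, 0.90, 0.96, 0.99), chosen so that high intake levels are
rare, as in real FFQs. Per-food amounts are frequency/day times a fixed
seeded portion weight with log-normal within-food variation; total energy
is a linear function of total amounts plus noise. The default planting —
four factors of six foods each with primary loadings 0.75 on a 24-food
list — gives a realistic but clearly recoverable factor-analysis problem.

*Outcome.* Within each pair the case label is drawn from the exact 1:1
conditional-logistic probability
`P(member 1 is the case) = exp(eta1) / (exp(eta1) + exp(eta2))` with
`eta = beta' z` on standardized planted exposures. The generator is thus
*exactly* the model the risk stage fits, which is what makes the coverage
and null-calibration checks meaningful. Tumor sites are multinomial over
proximal colon / distal colon / rectum (0.35/0.30/0.35 by default);
optional site-specific coefficients let one pair-level site be drawn first
so that site-stratified power can be tested.

*Metabolome.* Feature log-intensities are a per-feature baseline plus
`effect * z` for planted feature–exposure links plus normal noise (sd 1 by
default), exponentiated — so planted links are monotone on the raw scale.
Pooled study-QC (sQC) injections are replicates of the pooled mean profile
with relative technical noise `qc_cv` (default 0.10, so realized CVs sit
near 10 %). Missingness is completely at random at `missing_rate` among
study samples; intensity-dependent missingness and batch drift are
deliberate non-goals (batch correction is out of scope of this package).

What passing tests on these data show: the estimators recover known
structure under their own assumptions, at the planted effect sizes and
noise levels. What they do not show: robustness to non-normal intake
distributions, differential measurement error, batch effects, or
informative missingness, none of which the generator emulates.

## Dietary exposures

`map_frequency_levels()` maps the 9-level scale to times/day. Only the
endpoints are fixed by the instrument ("never" = 0, "≥ 4 times/day" = 4);
the interior values (0.5/month, 1–3/month, 1/week, 2–3/week, 4–6/week,
1/day, 2–3/day) follow common FFQ conventions and are an explicit,
overridable assumption. `energy_adjust()` implements the energy-density
method per 1000 kcal — kcal rather than MJ because energy intake is
conventionally reported in kcal/day in this literature.

A deliberate design choice: **pattern derivation operates on the reported
9-level frequency codes, not on the mapped times/day values.** The times/day
map is nearly exponential (0, 0.017, …, 2.5, 4), which concentrates mass
near zero, skews the food distributions, and measurably attenuates Pearson
correlations and factor-score determinacy (on planted data, score–truth
correlations drop from ≈ 0.95 on the level scale to ≈ 0.75 after the map).
The ordinal codes are approximately quantile-spaced and carry the latent
structure much more faithfully into a correlation-based factor analysis.
Mapped and energy-adjusted frequencies remain available from
`derive_exposures()` for descriptive use.

`categorize_alcohol()` returns zero / below / above the sex-specific
non-zero median; values exactly at the median are "below" (an arbitrary,
documented, configurable tie rule). The zero category exists because
non-consumers are an etiologically mixed group.

## Pattern derivation: repeated half-split EFA/CFA

`stability_select()` repeats `n_rep = 5` times: a seeded random 50/50
participant split (pairs are not kept intact — pattern discovery concerns
individuals, not the matching); for each factor count `k` in `k_range`
(default 2–18, clipped to counts leaving non-negative ML degrees of
freedom), maximum-likelihood EFA on half 1 (`stats::factanal`) followed by
oblimin rotation, implemented as gradient projection on the oblique
manifold with `gamma = 0` (direct quartimin, the conventional default) and
a deterministic column-sign convention; a CFA on half 2 using, per factor,
the foods with |loading| > 0.3 (factors retaining fewer than two foods are
dropped).

The CFA is a maximum-likelihood fit of `Sigma = Lambda Phi Lambda' + Psi`
to the sample correlation matrix, identified by fixing factor variances at
1 so loadings are comparable across factors; factor correlations and
uniquenesses are free (uniquenesses bounded below at 0.005 — the Heywood
guard, matching the EFA's bound, which is flagged with a warning when
active). Optimization is L-BFGS-B with analytic gradients
(`dF = tr(W dSigma)`, `W = Sigma^-1 - Sigma^-1 S Sigma^-1`). Models with
more free parameters than correlation moments raise an explicit
underidentification error — this is what keeps junk two-food factors from
noise data out of the stability pool.

*Combined fitness.* The paper-style "combined assessment of averaged
fitness measures" is implemented as the rank average of mean CFI, TLI,
RMSEA and SRMR across repeats (best rank picks `k_best`); the *plateau* of
comparably fitting `k` is defined on the composite
`(CFI + TLI + (1 - RMSEA) + (1 - SRMR)) / 4` within `plateau_tol = 0.01`
of the best. Factors from all repeats and all plateau `k` are pooled and
clustered greedily by Tucker congruence |φ| ≥ 0.85 (sign-aligned; clusters
whose mean vectors still agree are merged). Only clusters containing
factors from **all** repeats become patterns — an empty result is a valid
`pattern_set`, not an error. A final CFA of the stable structures on all
participants yields regression (Thurstone) factor scores, zero-mean by
construction. The φ ≥ 0.85 matching threshold, like the score method and
the use of the final all-data CFA for scores, fills gaps the source
procedure leaves open; all are configurable.

## Risk models

`fit_clogit()` standardizes the exposure to unit SD over all analyzed
participants after pair-completeness filtering (controls-only SD is
available as an option; which SD to use is genuinely underdetermined) and
maximizes the exact 1:1 conditional likelihood via `survival::clogit`.
Covariates: continuous BMI and energy; smoking, physical activity and
education as unordered indicators with the first level as reference;
categorized alcohol — excluded automatically when the exposure itself is
alcohol. Pairs with any missing covariate are dropped whole. Wald 95 % CIs
(β ± 1.96 SE) are reported; no multiplicity correction (the analyses are
exploratory by design, nominal p < 0.05). An exposure with no within-pair
contrast returns OR = 1 with a flat CI exactly, since the conditional
likelihood carries no information about it. Sex strata retain whole pairs
(pairs are sex-matched); site strata keep pairs whose case has that site,
excluding unknown sites; strata under 10 pairs are flagged unstable but
still returned.

## Metabolite preparation

`cv_filter()` removes features whose sQC coefficient of variation (sd/mean
on raw intensities — the conventional definition; a log-scale option is a
documented alternative) exceeds 0.30; zero-mean features are removed as
"undefined CV". The filter is idempotent and monotone in the threshold.

`rf_impute()` is a missForest-style iterative imputer: feature-median
initialization, feature-by-feature random-forest regression on all other
features (100 trees, `mtry = sqrt(p)`, seeded, single-threaded for
determinism), visiting features in order of increasing missingness, and
stopping at the first sweep where the normalized change in imputed cells
rises (returning the previous sweep) or after `max_iter = 10`. Observed
cells are never modified, bitwise.

## Diet–metabolome association

`rdcv_rf()` is a repeated double cross-validation frame: outer folds
(default 6) are held out entirely; within each outer training set an inner
CV (default 5 folds) tunes recursive variable elimination by random-forest
impurity importance, keeping `var_ratio = 0.75` of the variables per step
down to 2. The minimal-optimal size — the smallest ladder size attaining
the minimum inner CV error — is refit on the full outer training set and
predicts the held-out fold. Q² = 1 − PRESS/TSS is computed on out-of-fold
predictions per repetition (default 10) and averaged. The consensus
selected set takes the top `round(mean(model sizes))` features by selection
frequency (importance as tie-break). Forests use 300 trees and
`mtry = p/3` (regression convention), all seeded. The repetition, fold,
ratio and tree counts are explicit assumptions — the cited framework's
exact settings are not published — and are arguments, not constants.

`permutation_test()` re-runs the whole rdCV on permuted responses
(default n = 50). Both the empirical p, floor-bounded at `1/(n_perm + 1)`,
and a parametric p from a normal fit to the permuted-Q² null are reported:
the parametric value is what allows p-values far below the empirical floor
to be quoted from a 50-permutation design.

`partial_spearman()` rank-transforms the feature, the exposure, *and all
numeric covariates* (factors become indicator contrasts), residualizes the
two targets on the covariate design, and correlates the residuals, with a
t-approximation on `n − 2 − q` degrees of freedom. Ranking the covariates
matters: residualizing ranks on a *raw* normal covariate leaves the
nonlinear part of the rank map in both residuals and can fabricate partial
correlations of ≈ 0.1 out of pure confounding. With no covariates the
function reduces exactly to the ordinary Spearman correlation. Zero
residual variance yields an explicit null record rather than an error.

`select_diet_features()` applies the screening cascade — Q² > 0.15,
permutation p < 0.05, partial-Spearman validation p < 0.05 — and collapses
features selected for several exposures to unique ids with all exposure
tags, mirroring the overlap expected between, e.g., an alcohol pattern and
total alcohol intake. Relaxing either threshold can only grow the set.

## Triplot

`pca_selected()` autoscales the selected features before decomposition —
LC–MS intensities differ by orders of magnitude across features, so
unscaled PCA would be dominated by a few high-intensity features (whether
the original analysis scaled or only centered is unstated; autoscaling is
the defensible default). Component signs follow the same
dominant-loading-positive convention as the factor analyses, making all
downstream tables reproducible across platforms. `component_associations()`
runs the conditional-logistic and partial-Spearman machinery on the first 3
components (the range typically reported), and `export_triplot()` /
`read_triplot()` round-trip the plot-ready tables.

## Problem sizes and determinism

The test suite and the acceptance script run the whole chain at desk scale:
hundreds to a few thousand pairs, tens to a couple of hundred metabolite
features, rdCV with 1–3 repetitions and 30–100 trees, 20 permutations.
These sizes were chosen so the full verification battery — including 200
coverage replicates and 20-seed pattern-recovery and null-control sweeps —
completes in minutes while leaving all effect-size and noise parameters at
their defaults; every statistical procedure scales to full-size data by
raising its arguments. Every stochastic step takes an explicit seed
(refusing to run without one), random forests run single-threaded with
fixed seeds, and written tables are plain TSV, so a pipeline run is
byte-reproducible: the same seed gives identical files.

## Known limitations

- The FFQ interior frequency values and the rdCV settings are documented
  assumptions, not published values.
- Factor matching across splits uses Tucker congruence with a fixed
  threshold; human inspection in the original workflow may merge or split
  constructs differently.
- MCAR missingness and sQC-only QC structure are simplifications; batch
  correction, peak picking and metabolite annotation are explicitly out of
  scope.
- Matched sets beyond 1:1, time-to-event outcomes, and
  multiple imputation of covariates are not supported.
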