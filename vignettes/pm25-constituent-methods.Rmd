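---
title: "Methods: PM2.5 constituent mixtures and predicted 10-year ASCVD risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PM2.5 constituent mixtures and predicted 10-year ASCVD risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm25ascvd)
```

## The scientific problem

Fine particulate matter (PM2.5) is a mixture. Its six major chemical
constituents — black carbon (BC), ammonium (NH4+), nitrate (NO3−), organic
matter (OM), sulfate (SO42−), and soil particles (SOIL) — differ in sources
and toxicity, and regulating total mass alone cannot say *which* fraction of
the mass is worth removing first. This package implements a cross-sectional
analysis pipeline that relates long-term (multi-year averaged) exposure to
PM2.5 and its constituents to a binary outcome: whether a participant's
predicted 10-year risk of atherosclerotic cardiovascular disease (ASCVD),
from a Cox-score risk equation, is high (≥ 10%).

Constituent concentrations are strongly mutually correlated (they share
meteorology and sources), so single-pollutant effect estimates are
confounded by total mass and by each other. The pipeline therefore
implements the three standard single-constituent parameterizations plus an
explicit reallocation model:

* **Concentration analysis** — logistic regression of the outcome on one
  pollutant's absolute concentration (per 1 µg/m³).
* **Proportion analysis** — the exposure is the constituent's share of total
  mass in percent (per percentage point), adjusted for total PM2.5 mass.
* **Residual analysis** — the exposure is the residual of the constituent
  regressed (OLS) on total mass, which is exactly uncorrelated with total
  mass by construction; total mass is not additionally adjusted for.
* **Isochronous substitution model (ISM)** — drop one constituent from a
  model that contains total mass and the five others. Holding total mass
  and the other constituents fixed, a retained constituent's coefficient is
  the effect of *replacing* 1 µg/m³ of the dropped constituent with
  1 µg/m³ of the retained one: `OR(j→k) = exp(β̂k)` in the model dropping
  `j`.

Each analysis is fit unadjusted (Model 1) and adjusted (Model 2) for
gender, marital status, educational level, average monthly income, physical
activity, high-fat diet, drinking status, and high fruit and vegetable
intake. Effects are reported as odds ratios with Wald 95% confidence
intervals (`exp(β̂ ∓ 1.96·SE)`).

## The outcome: a table-driven 10-year risk engine

Predicted 10-year ASCVD risk comes from a sex-specific Cox-score equation:

`risk = 1 − S0 ^ exp(LP − LP̄)`,

where `LP = Σ βi·gi(xi)` over a table of terms (transforms: identity, log,
0/1 indicator, and products for interactions), `LP̄ = Σ βi·x̄i` uses the
score's published cohort means, and `S0` is the baseline 10-year survival.
Risk is classified *high* at the 10% threshold, inclusive
(`risk ≥ 0.10 → high`).

The engine is deliberately table-driven: the published China-PAR
coefficients are not reproduced in any source this package ships with, so
hard-coding them would amount to inventing numbers. The package instead
ships a schema (JSON) plus a clearly labelled *synthetic* example table
(`inst/extdata/synthetic_risk_coefficients.json`, loaded by
`example_risk_table()`) that exercises every transform; users drop in the
published coefficients in the same schema. How "region" and smoking are
coded in the published score is likewise left to the table rather than
assumed. Physiological range checks are warnings, not errors.

## The synthetic cohort generator

The analysed cohort (31,162 rural adults aged 35–74, after excluding 476
with missing risk predictors, 3,537 outside the age window, and 4,084 with
prior ASCVD from 39,259 enrolled) is not publicly deposited. The generator
therefore emulates the *published statistical structure*, so that every
downstream stage is testable end to end:

* **Exposures.** A Gaussian copula: a multivariate normal draw with a
  one-factor correlation matrix (`corr[j,k] = λj·λk`, loadings 0.72, 0.99,
  0.995, 0.93, 0.96, 0.73) mapped through per-constituent marginal
  quantile functions. Defaults are normal margins truncated at zero with
  the published 3-year-average means/SDs (e.g. BC 5.190 ± 0.947, NO3−
  18.016 ± 2.619 µg/m³); a moment-matched lognormal margin is available.
  The loadings were chosen once so the pairwise correlations span
  ≈ 0.53–0.99, inside the published 0.51–0.99 range; the exact empirical
  matrix is unpublished. Truncated margins solve for the pre-truncation
  location whose *post*-truncation mean equals the configured mean, so
  configured means are honoured exactly.
* **Mass closure.** The published constituent means sum to 73.838 µg/m³
  against a total of 75.238 µg/m³, so the default `residual_mass` mode adds
  an independent truncated-normal unapportioned mass (mean 1.400, SD 1.5
  µg/m³) to the constituent sum. The alternative `exact_sum` mode makes
  total ≡ sum, which is what makes the ISM identities below exact.
* **Covariates.** Categorical frequencies are stored as printed count /
  31,162 (so they sum to one exactly); continuous risk factors are normal
  (age truncated to [35, 75); the others floored at zero); binary risk
  factors are Bernoulli.
* **Outcome.** The default mechanism is logistic:
  `Y ~ Bernoulli(expit(α + Σ βx))` with the intercept α calibrated by
  bisection on [−20, 20] (tolerance 1e-4 in prevalence) so the expected
  prevalence equals the target, 28.143%. The default truth places the
  whole exposure effect on BC at `log(1.493)` per µg/m³ — the strongest
  published adjusted constituent association — because no generating
  mechanism is published and a single-constituent truth anchored to a
  printed value is the most interpretable choice for recovery tests. A
  `chinapar` mechanism instead scores participants with a coefficient
  table and thresholds at 10%.

What the generator does **not** emulate: spatial structure and
exposure–covariate confounding (e.g. region-driven correlation between
income and exposure), measurement error of the exposure surface, missing
data, and any true nonlinearity or effect modification (unless injected
through `true_beta` / custom outcome draws). Passing tests therefore show
that the *estimators* are correct and calibrated under the assumed
structure, not that the published effect sizes are externally reproduced:
the published headline odds ratios (e.g. BC Model 2 1.493 (1.446, 1.542))
depend on the real cohort's joint distribution and are carried in
documentation as reference output shapes only.

## Multi-year exposure averaging

Long-term exposure is the arithmetic mean of exactly `years × 12` monthly
values ending with the month *before* the baseline month (exposure accrues
prior to the baseline investigation; the baseline month is excluded).
Windows of 3 (main), 5, 8, and 10 years (sensitivity) are supported;
insufficient coverage is an error naming the first missing month, or an
audited per-participant exclusion in the sensitivity driver.
`generate_monthly_series()` expands a cohort's cross-sectional exposures
with an optional trend, a 12-month seasonal cosine, and multiplicative
noise; with all three at zero the window means reproduce the
cross-sectional values exactly, which pins the sensitivity machinery in
tests.

## Numerical choices

* **Fitting.** Logistic models are fit by `stats::glm.fit` (IRLS, deviance
  tolerance 1e-12) followed by a few guarded Newton steps until the score
  norm is below 1e-10. The polish matters: the ISM reparameterization
  identity is an exact-MLE property, and solver slack is what limits how
  tightly it can be observed. Rank deficiency is an error; condition
  numbers above 1e8 warn (the ISM designs are intentionally
  near-collinear); separation (fitted probabilities pinned at 0/1 with
  runaway coefficients) flags the fit as non-converged, never silently.
* **Test oracle.** `oracle_fit()` maximizes the same likelihood by
  derivative-free search (golden-section in 1D; Nelder–Mead restarts plus
  cyclic coordinate refinement otherwise), restricted to ≤ 30 rows × ≤ 4
  columns. It exists solely to cross-check `fit_logistic()` by an
  independent route.
* **ISM identities.** Under exact closure the leave-`j`-out model with
  total mass is an exact reparameterization of the all-constituent model
  without total, giving `β̂k(−j) = β̂k − β̂j`, reciprocity
  (`log OR(j→k) = −log OR(k→j)`) and transitivity; the suite verifies all
  three to 1e-6. With residual mass (the realistic default) the identities
  hold only approximately, and the observed reciprocity deviation scales
  with the residual-mass share — the exported matrix carries condition
  numbers so users can see how collinear each fit was.
* **Residual method.** OLS orthogonality (`corr(r, m) = 0`, zero mean) is
  exact and tested at 1e-10. Note that in a *logistic* model orthogonal
  regressors decouple only asymptotically; the exact invariance to adding
  total mass holds in the linear model, and the suite tests exactly that
  plus the asymptotic logistic version.
* **Splines.** Restricted cubic splines use the truncated-power basis
  (normalized by `(tK − t1)²`), default K = 4 knots at the
  5th/35th/65th/95th percentiles, reference at the sample median, and a
  100-point OR grid between the 1st and 99th percentiles (tail
  extrapolation distorts curves). Knot count/placement and the reference
  used in the original figures are unpublished, so curves are comparable
  only qualitatively. Nonlinearity is a likelihood-ratio test of the K − 2
  nonlinear terms.
* **Interactions.** Subgroup differences are tested by LRT on exposure ×
  stratifier product terms in the pooled adjusted model (df = levels − 1);
  Wald on the product terms is available and agrees with the LRT at large
  n. Three-level stratifiers are tested with 2-df tests, not trend tests.
  The stratifier is excluded from its own stratum-specific covariate set.
* **Rounding.** Exported report tables round half-up to 3 decimals
  (matching the source tables' style); `percent_excess()` reports
  `(OR − 1)·100` to 1 decimal.

## Calibration checks and problem sizes

The test suite re-derives every closed form it asserts (2×2 cross-product
ratio, hand OLS residuals, truncated-power basis against an independently
coded formula, risk-score closed forms) and checks the stochastic
machinery at fixed seeds: Wald 95% CI coverage in [0.92, 0.975] over 500
replicates at n = 2,000; type-I error of the nonlinearity and interaction
LRTs in [0.03, 0.07] over 1,000 null simulations at n = 600 each; simulated
total PM2.5 mean within two standard errors of its configured value at the
full cohort size n = 31,162. The analysis drivers run at the full cohort
size except the monthly-series sensitivity stage, which uses a
5,000-participant subsample (the 120-month × 7-pollutant expansion
dominates memory, and the estimator is unchanged by the subsetting).

## Known limitations

* Cross-sectional by design: odds ratios, no incidence or survival
  modelling, no survey weights, no robust/clustered errors.
* No spatial exposure modelling, geocoding, or chemical-transport
  simulation; exposures enter as given.
* The concentration analysis is read as separate single-pollutant models
  (total PM2.5 in its own model, each constituent alone); co-adjustment
  for total mass is available behind `adjust_total = TRUE` since the
  published description is ambiguous on this point.
* No multiplicity correction across the stratifier × pollutant grid (none
  was applied in the source analysis); no additive-scale effect
  modification; no quantile-based mixture methods (WQS, quantile
  g-computation) — the ISM is the only reallocation model implemented.
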