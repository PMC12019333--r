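---
title: "Methods: principal-component clinical age clocks in pcclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: principal-component clinical age clocks in pcclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcclock)
```

## The model

`pcclock` trains clinical biological-age clocks of the kind built on
routinely collected laboratory, examination and questionnaire parameters.
The chain is:

1. **Curation and robust normalization.** Each parameter is optionally
   log-transformed (for right-skewed, strictly positive analytes), then
   z-scored against a *young, generally healthy reference stratum* —
   subjects aged 40–49 years, separately for males and females — using the
   median and the median absolute deviation (MAD):
   \[ z = \frac{T(x) - \mathrm{median}_{\mathrm{ref}}}{c \cdot
      \mathrm{MAD}_{\mathrm{ref}}}, \]
   with \(c = 1.4826\) so the scaled MAD estimates the standard deviation
   under Gaussian data. Normalizing to a fixed young-adult reference makes
   z-scores comparable across survey waves and mitigates batch effects.
   Outliers are capped at \(\pm 6\) robust SDs *after* standardization
   (capping in z-space is the only scale on which "six standard
   deviations" is meaningful). Missing values are imputed at \(z = 0\)
   (the reference median); subjects missing more than 20% of parameters
   are dropped rather than imputed.

2. **Sex-specific SVD.** The normalized matrix is column-centered per sex
   and factorized \(X = USV^\top\). Loadings are the right singular
   vectors; components are named `PC1M, PC2M, ...` (males) and `PC1F, ...`
   (females). Each loading column's sign is fixed so its
   largest-magnitude entry is positive — singular-vector signs are
   arbitrary, and reproducible loading interpretation needs a convention.
   Training column means are stored so new subjects project consistently.

3. **Cox weights.** A Cox proportional-hazards model (Efron tie handling)
   on the selected PC scores, per sex, gives the weights \(\beta_k\); the
   linear predictor \(\eta = \sum_k \beta_k p_k\) is the clock's risk
   score. Chronological age (CA) is *not* a covariate: the ideal clock
   captures the biology directly and would assign CA negligible weight.
   An `include_ca = TRUE` flag exists for ablation studies only.

4. **Gompertz age mapping.** A null Cox model with CA as the sole
   covariate estimates the Gompertz slope \(\gamma\) (the mortality-rate
   doubling time is \(\mathrm{MRDT} = \ln 2/\gamma\), about 8 years in
   human populations). Biological age is
   \[ \mathrm{BA} = \mathrm{CA} + \frac{\eta -
      \hat\eta(\mathrm{CA})}{\gamma}, \]
   where \(\hat\eta(\mathrm{CA}) = a + b\,\mathrm{CA}\) is the ordinary
   least-squares fit of \(\eta\) on CA in the training cohort. This
   realizes the definition of biological age as *the age at which the
   reference cohort carries the subject's mortality risk*, under
   proportional hazards: adding \(\ln 2\) to \(\eta\) (one hazard
   doubling) adds exactly one MRDT to BA. Per-PC contributions
   \(\beta_k p_k/\gamma\) (in years) decompose the age delta exactly:
   \(\sum_k \beta_k p_k / \gamma - \hat\eta(\mathrm{CA})/\gamma =
   \mathrm{BA} - \mathrm{CA}\).

### Design choices where the design was genuinely open

* **Centering.** Age-conditional centering (OLS of \(\eta\) on CA) is the
  default: it forces the mean age delta to zero at every age, so deltas
  are comparable across the age range. A `"global"` option (mean-\(\eta\)
  centering, no age term) is provided for users who prefer a
  population-level anchor.
* **MAD constant.** The robust z-score could use the raw MAD; we use
  \(1.4826 \cdot \mathrm{MAD}\) (configurable) so that the six-SD cap and
  MAD-based z-scores are commensurable.
* **Order of operations.** Transform, then reference statistics, then
  z-score, then cap. Reference statistics are computed pre-capping;
  capping affects well under 1% of reference-stratum values under
  Gaussian-like noise, and the reference stratum therefore retains median
  0 / scaled MAD 1 per column exactly (verified to 1e-10 in the tests
  when no values are missing).
* **Component selection.** No universal rule exists for which "aging
  PCs" to keep. The default retains components individually associated
  with all-cause mortality in univariate Cox fits at Benjamini–Hochberg
  FDR < 0.05, per sex — mortality association matches the training
  target. `"all"`, `"top_k"` and `"age_cor"` policies are selectable, and
  the per-component statistics are kept in the fitted object.
* **Weight scale.** Cox weights apply to raw PC scores as produced by
  projection (declared in the bundle metadata as `score_scale: "raw"`),
  so published coefficient tables can be dropped into a bundle verbatim.
* **Plausibility.** Scored BAs are never clamped. Deltas above +35 years
  or BAs above 105 years — outside the range observed in validation
  cohorts even for seriously ill subjects — trigger a warning only.

## Benchmarking machinery

* **k-year mortality labels.** A subject dead at or before the horizon is
  a case; one observed past it, a control; one *censored before* the
  horizon carries no usable binary label and is excluded (the
  simple-exclusion convention — inverse-probability-of-censoring
  weighting is out of scope; the exclusion counts are always reported).
* **AUC.** Mann–Whitney with midrank ties; exactly the probability a
  random case outscores a random control, ties counted half.
* **DeLong's test** for correlated AUCs is implemented from the
  structural components (the returned object includes the full 2×2
  covariance of the AUC pair); `pROC` and a 10 000-resample paired
  bootstrap serve as independent cross-checks in the test suite.
* **Reference clocks.** `ChronAge` is CA itself; `RandomAge` adds
  Gaussian noise (default SD 10 years) to CA — a degraded-information
  floor; `CrystalAge`, defined only on synthetic cohorts, orders subjects
  by their true uncensored death time and is the AUC-1 ceiling.
* **Quartile-stratified survival.** Within 10-year CA bins, each clock's
  lowest and highest 25% are compared by Kaplan–Meier curves (Greenwood
  bands) and pairwise log-rank tests, Benjamini–Hochberg-adjusted within
  the *bin's* family of comparisons (one figure panel = one family; the
  family is explicit, never implicit). Quartile-boundary ties are broken
  by subject-id order for reproducibility. Different clocks' quartiles
  overlap in membership; the log-rank test compares the selected groups
  as sampled.

## Interpretation machinery

PC–outcome heatmaps fit one multivariate logistic regression per binary
outcome with all selected PCs as simultaneous covariates, per sex.
Display truncation follows the conventions of the field's figures:
coefficients with \(p \ge 0.05\) are shown as zero; for cause-of-death
outcomes, negative (protective) associations are also zeroed — "no harm"
is the conservative display for a cause-specific risk map; disease and
sociological outcomes keep signed values clipped to \([-1, 2]\) for a
common color scale. Truncation is display-layer only: raw coefficients,
SEs and p-values are always retained. No multiplicity correction is
applied across cells by default (the display rule is a raw per-cell 0.05;
a BH switch exists). We fit binary one-vs-rest logistic models rather
than one multinomial model; for the per-outcome log risk ratios displayed
per row the two parameterizations agree — this equivalence is an assumption
we declare rather than prove. Disease associations are taken against
baseline-prevalent status.

Per-subject reports decompose the age delta into per-PC year
contributions and, for every PC contributing at least one year (in either
direction), list the parameters with \(|\mathrm{loading}| \ge 0.1\) —
magnitude, not signed value, since parameters drive a component in both
directions — together with the subject's raw values.

Healthspan markers: the raw digit-symbol-substitution score; gait speed
as 6.096 m (20 feet) divided by the timed-walk seconds; ability to work;
and the iADL/bADL composites, where a subject is "able" only if every
item in the set is at worst "some difficulty". Any missing required item
leaves the composite missing.

## The synthetic-cohort generator

The generator emulates the *structure* of a population survey cohort with
linked mortality follow-up; it makes no attempt to match any real
cohort's marginal distributions parameter-by-parameter. Defaults, chosen
once as the study conditions:

| field | default | rationale |
|---|---|---|
| ages | uniform 30–84 y | adult survey range below the top-coding age (85) |
| sex ratio | 0.5 | balanced strata |
| parameters | 60 (first third log-normal) | a curated clinical panel's size; skewed analytes get log transforms |
| latent factors | 3, strengths 1.3 × 0.75^(k−1) | a dominant cardiometabolic-like axis plus weaker axes; *distinct* strengths keep the factor structure identifiable (equal strengths make sample PCs an arbitrary rotation of the latent subspace, so no method could recover them) |
| age slopes | uniform 0.002–0.02 SD/y, 70% positive | modest drift so PCs correlate with CA, without the dense age direction colliding with a latent block's eigenvalue |
| noise SD | 1 | per-parameter residual on the standardized scale |
| Gompertz slope | ln 2 / 8 per year | the ~8-year doubling time of adult human mortality |
| baseline hazard | 3 × 10⁻⁵ /y at age 0 | gives ~25% 20-year mortality in a 30–84 cohort, survey-like |
| latent log-hazard effects | 0.5, 0.35, 0.2 per SD | strong but realistic risk-factor gradients |
| follow-up | 20 y administrative censoring | a long mortality-linkage window |
| missingness | 2% MCAR | sporadic lab/questionnaire gaps; informative missingness is out of scope |

Death times are drawn *exactly* by inverse transform from the closed-form
Gompertz cumulative hazard (no discrete-time approximation, so doubling
-time recovery tests carry no step-size artifact). Healthspan fields
worsen with latent burden and age through logistic models, so
interpretation analyses have planted signal to find. The uncensored death
time and the true latents ride along as ground truth (`true_death_time`,
attribute `"latents"`) — things no real cohort carries, which is exactly
why `CrystalAge` exists only here.

**What passing tests on this generator do and do not show.** They show
the estimators are correct under the model's own assumptions
(proportional hazards, linear factor structure, MCAR missingness,
administrative censoring at one horizon). They do not show robustness to
informative censoring or missingness, non-proportional hazards, U-shaped
risk, assay batch effects beyond a location/scale shift, or the messy
marginals of real laboratory data.

**A note on the null-model check.** With unobserved latent risk factors,
the *marginal* hazard is no longer exactly Gompertz: frailty flattens the
observed age slope (in our defaults, the CA-only Cox model recovers an
MRDT near 8.8 y rather than 8 y). The doubling-time recovery check is
therefore run on homogeneous cohorts (`latent_effects = 0`), where the
Cox age coefficient is consistent for the true slope; the heterogeneous
case is covered by the empirical person-year hazard regression test with
a 15% band. This attenuation is a property of Gompertz-frailty mixtures,
not of the estimator.

## Numerical choices

* Cox ties: Efron approximation (the standard default).
* SVD via LAPACK through base `svd`; reconstruction is verified to
  1e-8 and loading orthonormality to 1e-8 in the tests.
* Logistic separation in heatmap fits: coefficients with |coef| > 15 or
  SE > 15 are flagged and zeroed in the display (with a warning), never
  an abort.
* Degenerate DeLong variance (e.g. identical score vectors): reported as
  p = 1 with a `degenerate` flag.
* Zero-MAD parameters are rejected at reference fitting; log transforms
  refuse non-positive values.
* Serialization writes doubles with 17 significant digits (CSV and the
  JSON metadata, where they are stored as strings) so bundles and cohort
  files round-trip losslessly.

## Problem sizes used by the checks

The test suite and the acceptance script run on simulated cohorts of
2 000–5 000 subjects (20 000 for the empirical hazard regression), 20
replicate cohorts for doubling-time recovery, 20 replicate 50-cell null
panels (1 000 cells) for the heatmap false-positive rate — a Monte-Carlo
standard error of about 0.007 on the 0.05 rate — and 10 000 bootstrap
resamples for the DeLong cross-check. These sizes give sampling error
comfortably inside each check's band while keeping a full run in the
minutes range.

## Known limitations

* Linear dimensionality reduction conflates intrinsic aging with disease
  signatures and cannot represent U-shaped risk; this is the price of
  interpretability, and nonlinear embeddings are deliberately out of
  scope.
* The published 60-parameter manifest, loading and weight tables are not
  bundled; the bundle format accepts them verbatim, and clocks can be
  trained from any cohort table with a parameter manifest.
* Cause-specific analyses are association heatmaps, not competing-risk
  models; no causal reading is licensed.
* Censoring-before-horizon subjects are excluded from ROC labels rather
  than weighted; with heavy early censoring this can bias AUCs.
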