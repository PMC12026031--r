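---
title: "Methods: scoring CSF biomarker profiles and comparing dementia risk classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring CSF biomarker profiles and comparing dementia risk classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ersrisk)
```

This vignette documents the models, conventions and design choices behind
`ersrisk`: what is computed, which decisions were genuinely open, and what
the synthetic-cohort tests do and do not demonstrate.

## 1. Three-zone marker classification

Every analyte is judged against an assay-panel cut-off `c` with a
borderline band of half-width `f·c` (`borderline_fraction`, default 0.10).
`classify_marker_zone()` partitions the positive axis into clearly normal
(zone score 0), borderline (1, the closed band `[c(1−f), c(1+f)]`) and
clearly pathological (2, beyond the band in the pathological direction).
Alongside the zone, the plain binary status is kept: pathological iff the
value is *strictly* past `c`. A borderline value therefore sits on either
side of the binary cut — this distinction is what lets a profile be, say,
amyloid-negative by the binary call yet still collect one borderline point
in the score.

**Tie conventions (a package choice).** The verbal scoring rule does not
say what happens exactly at `c` or at `c(1±f)`. We fix: zone-edge ties
fall into the borderline zone; the binary call is strict, so a value
exactly at `c` is normal (for both directions), mirroring the one explicit
strictness cue available for the amyloid ratio ("pathological below" its
cut-off). All boundaries are thereby deterministic, and scoring is
invariant under common rescaling of value and cut-off.

**Sidedness of the borderline band.** The published prose describes the
Aβ1-42 band as "below the cut-off" and the tau band as "within 10%". We
implement a symmetric ±10% band for every analyte: the reference
cross-tabulation is only reproducible this way (it contains subjects
scoring a borderline point on the pathological side of the Aβ1-42 cut-off
and one subject scoring it on the normal side).

## 2. The Erlangen Score

`ers_score()` computes: amyloid sub-score = zone(Aβ1-42), tau sub-score =
max(zone(pTau181), zone(tTau)), sum in 0–4; then the amyloid-ratio
adjustment of +1 (ratio pathological) or −1 (ratio normal), with totals
clamped back into 0–4. High risk means total > 1.

One published description of the adjustment says the score is *decreased
by one if the ratio is negative and the sum score is less than one*; read
literally that produces totals of −1 and contradicts the add-then-clamp
description given elsewhere, which reproduces every cell of the reference
cross-tabulation. We implement add-then-clamp and treat the other wording
as a typographical slip.

Without Aβ1-40 the ratio adjustment is impossible; the unadjusted sum is
then read on a three-level scale. The mapping low = 0–1, medium = 2,
high = 3–4 is not spelled out in the sources; we chose it so that
"pathological = values above one" is preserved with a single intermediate
level. This only affects the `risk_class` label, never the total.

## 3. Youden calibration of the pTau/Aβ1-42 ratio

`calibrate_youden()` maximizes J = sensitivity + specificity − 1 over the
empirical thresholds, with cases = profiles with all four markers
pathological and controls = biomarker-negative profiles (both supplied by
the caller, so a larger external calibration pool can be used). Candidate
thresholds are midpoints between consecutive distinct pooled values plus
sentinels outside the data range; J ties break toward the candidate with
higher specificity, then the smaller cut-off. The tie policy is ours —
the index itself does not fix one — and makes calibration deterministic.
Classification is strictly above the cut-off. No smoothing or parametric
ROC is used; the calibration is purely empirical.

## 4. The trajectory mixed model

For subject $i$ at visit time $t$ (years),
$$z_{i,t} = \beta_0 + \beta_1 t + \beta_2' g_i + \beta_3' g_i t
          + u_{0i} + u_{1i} t + \varepsilon_{i,t},$$
with $(u_{0i}, u_{1i}) \sim N(0, G)$ and AR(1) residuals
$\mathrm{cov}(\varepsilon_{i,j}, \varepsilon_{i,k}) =
\sigma^2_e\,\rho^{|j-k|}$ over the within-subject visit order. MMSE
z-scores are consumed as given; demographic normalization of raw MMSE is
out of scope.

Choices that were genuinely open:

* **Time unit.** The sources describe follow-up time in months in one
  place but report per-year slopes; we fit in years (the reported scale).
  Rescaling is exact: fitting months-scaled times divides the slope terms
  by 12 and leaves the maximized likelihood unchanged (tested).
* **AR(1) over order vs elapsed time.** Default is visit order, the
  repeated-effects convention of the major mixed-model implementations; a
  continuous-time variant `rho^|Δt|` is available (`ar1 = "continuous"`).
* **Estimation.** Full ML (not REML), as the comparison relies on AIC/BIC
  across models with different fixed effects. Fixed effects are profiled
  out by GLS; the five covariance parameters are optimized on an
  unconstrained scale (Cholesky of $G$, Fisher-z of $\rho$, log residual
  SD) by `nlminb` from a deterministic OLS-based start, so fits are
  reproducible. Subjects sharing a visit-time pattern share one
  covariance factorization per likelihood evaluation, which keeps a
  259-subject fit well under a second.
* **Parameter count.** `n_params` = fixed effects + 5 covariance
  parameters ($G$ has three, plus $\rho$ and $\sigma^2_e$); BIC uses the
  total observation count. This matches the df convention of the
  independent mixed-model implementation used as a cross-check in the
  test suite.
* **Inference.** Wald z tests and normal CIs from the asymptotic GLS
  covariance at the ML estimates; no small-sample df correction.

`rmse()` reports marginal (fixed-effects-only) and conditional (plus
empirical-Bayes random effects) root-mean-squared error;
`compare_lmm()` tabulates AIC/BIC/RMSE across score-defined groupings
fitted to identical visits.

## 5. Dementia risk: Cox, ROC, DeLong, diagnostics

Variable follow-up makes raw conversion flags incomparable across
subjects, so discrimination is assessed through a Cox model on the score
(Breslow ties and baseline) and the implied conversion probability at a
10-year horizon, $1 - \exp(-\Lambda_0(h)e^{\beta x})$. The horizon
default follows the published analysis and is configurable. Since the
probability map is strictly monotone in the score whenever $\beta > 0$,
the Cox step calibrates probabilities but provably cannot change the
empirical AUC — a property the suite asserts exactly. Covariate coding:
the ordinal score 0–4 enters as a numeric covariate (the only coding that
yields a five-point ROC), the ratio as continuous.

`delong_compare()` implements the paired AUC comparison from placement
values; `diagnostic_table()` the 2×2 summaries with the Haldane–Anscombe
0.5 correction (flagged) when a cell is empty.

The reference cohort's published AUCs, DeLong p-values and odds ratios
cannot be recomputed here because the patient-level data are not
deposited; the package instead verifies each estimator against an
independent oracle (all-pairs AUC enumeration, brute-force placement
components, grid-search partial likelihood, permutation-null uniformity
of the DeLong p-value) and checks estimator calibration on simulations
with known truth.

## 6. The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes; its
defaults are the study conditions and are not tuned per run:

* **Constellations.** 259 subjects drawn over the 13 observed ATN(R)
  constellations with weights equal to the reference cross-tabulation
  totals (87, 1, 5, 5, 3, 2, 2, 3, 58, 30, 9, 18, 36).
  `table1_fixture()` provides the deterministic exact-count version; its
  `borderline_variant` places the single borderline-normal Aβ1-42 value
  that the reference table's one maximum-score incongruent subject
  requires.
* **Value placement.** Analytes are drawn log-uniformly inside the zone
  their constellation requires, with a 2% interior margin so no generated
  value is an edge case; Aβ1-40 is set so the amyloid ratio lands clearly
  on the required side. Consequently recovering the requested
  constellation is an identity by construction. The per-subject
  pTau/Aβ1-42 ratio is a *consequence* of these draws: the generator
  does not force the reference table's ratio-row split, which depended on
  unpublished per-subject values.
* **Trajectories.** Annual visits at 0, 1, 2, … years truncated at the
  subject's follow-up end, simulated from the mixed model above; default
  truth uses the published binary-grouping fixed effects
  (−1.30, −0.07, −0.40, −0.40) with var(u₀) = 1.0, var(u₁) = 0.02,
  cov = 0, ρ = 0.3, σ²ₑ = 0.25 — variance settings chosen once as
  plausible for z-score data of this kind (between-subject SD ≈ 1,
  slope SD ≈ 0.14/y, moderate residual autocorrelation).
* **Follow-up.** Durations are drawn from a piecewise-linear quantile
  function through (0, 1), (0.25, 1.6), (0.5, 3.25), (0.75, 6.5),
  (1, 13) years: the published median (3.25) and IQR (4.9) hold exactly
  by construction on the eligible 1–13-year range; the two interior
  knots are otherwise arbitrary.
* **Outcomes.** Exponential conversion times with rate
  `baseline_rate · exp(log_hr · group)`, censored at follow-up end.
  Defaults log HR = log 3 and baseline rate 0.0554/year, the latter
  solved once (numerically, under the 156/103 group split and the
  follow-up distribution) so the expected conversion fraction equals the
  reference 81/259 ≈ 31%.
* **Visit frequency** in the real cohort is unstated; annual is assumed.

What passing tests on these cohorts shows: the estimators recover known
truth under the assumed data-generating process, and the scoring engine
reproduces the published cross-tabulation surface. What it does not show:
performance under assay drift, inter-laboratory variation, non-Gaussian
cognitive trajectories, informative censoring, or competing risks — none
of which the generator emulates.

## 7. Numerical conventions and degenerate inputs

* Likelihood evaluations reject non-PSD $G$, $|\rho| \ge 1$ and
  non-positive residual variance; the optimizer never sees those regions
  thanks to the unconstrained reparameterization. A non-convergent fit is
  returned flagged (`convergence != 0`) with a warning, not silently.
* Youden calibration with indistinguishable samples reports J = 0 with a
  degenerate-separation warning. DeLong comparisons with zero variance of
  the AUC difference (e.g. identical scores) return a degenerate flag and
  `NA` p-value. Cox monotone separation is flagged.
* Readers reject decimal-comma numerics, orphan visit/outcome rows,
  missing baselines, non-monotone visit times and duplicate
  subject-panel rows, each with a line-numbered message; multi-panel
  subjects resolve by a configurable panel priority list.
* Problem sizes used by the test-and-acceptance machinery: 100 simulated
  cohorts of 259 subjects per recovery check, 10,000 random profiles for
  the scoring oracle, 1,000 draws for the calibration oracle, 1,000
  permutations for the DeLong null — sizes chosen so Monte-Carlo error is
  far below the tolerances being asserted.

## 8. Known limitations

* Inference in the mixed model is asymptotic (Wald/normal); no
  Satterthwaite or Kenward-Roger corrections.
* No REML, no random effects beyond intercept and slope, no imputation of
  missing visits, no time-varying covariates or competing risks.
* The three-level ratio-free risk mapping and the cut-off tie conventions
  are package choices (Sections 1–2); both are documented flags, and
  alternative assay cut-offs are user-suppliable per panel.
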