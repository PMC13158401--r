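---
title: "Methods: additive EV + serology scoring for LR-M lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: additive EV + serology scoring for LR-M lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evscore)
```

## Scope and model

`evscore` develops and certifies integer additive point scores that
separate hepatocellular carcinoma (HCC, label 0) from intrahepatic
cholangiocarcinoma (iCCA, label 1) in LI-RADS LR-M lesions, from a panel
of six routine serological markers and three CD133/2⁺ small-EV
subpopulations. The pipeline has five stages — prioritize, build, evaluate,
certify, explore survival — each of which is an exported function with its
own contract, so stages can be rerun or swapped in isolation.

The classification model underlying the score is penalized logistic
regression on z-scored markers,

$$\min_{\beta_0,\beta}\; \frac{1}{n}\sum_i \left[\log(1+e^{\eta_i}) -
y_i\eta_i\right] + \lambda \sum_j |\beta_j|, \qquad
\eta_i = \beta_0 + x_i^\top\beta,$$

with an unpenalized intercept. The additive score discretizes the selected
markers: marker $m$ contributes one point when its native-unit value lies
strictly above its cut-off $c_m$, and the patient is called iCCA when the
total reaches an integer threshold $T$.

## Preprocessing and leakage control

Standardization and imputation are fitted on the training split only.
Disease-stratified median imputation (the default for training data)
consults the diagnosis label, which is unknown at prediction time; test
and prediction data therefore use `leakage_safe` imputation — overall
medians of the training split. Both modes are exported because the
stratified variant is needed to replicate the original workflow
faithfully. The standard deviation estimator is the sample (n − 1) form,
conventional for z-scoring small cohorts. Splitting is stratified by class
by default: with 25 patients per class, an unstratified 80:20 split can
leave a test part without one class, making AUROC undefined.

## Marker prioritization

The penalty $\lambda$ for the single reported model is chosen by
stratified 5-fold cross-validation on the training split, maximizing mean
held-out AUROC, with ties broken toward the larger penalty (the sparser
model). The solver is an iteratively reweighted least squares scheme with
inner cyclic coordinate descent; when the IRLS surrogate fails to certify
descent (saturated fits near separation) the step is retaken with constant
majorant weights 1/4, which globally upper-bound the logistic curvature,
and near the optimum — where the objective is flat to machine precision —
steps are accepted by Karush–Kuhn–Tucker (KKT) residual decrease. The
contract is the objective plus KKT conditions at tolerance 1e−8 (iteration
cap 1e5), not the algorithm; the test suite checks the KKT system directly
and cross-checks coefficients against an independent implementation.

PCA contributions are $c_m = \sum_{k \le 4} |w_{mk}|$ over the first four
principal components of the column-standardized matrix; components of
numerically zero variance are dropped before summing, so the score is
well-defined on rank-deficient panels and invariant to component sign
flips. The final selected set is the union of the L1 support with the
top-$q$ markers by contribution ($q = 5$ by default, the length of the
top-contribution list the workflow reports); the exact merge rule is a
design choice documented here because no canonical rule exists. Ranks are
lexicographic: non-zero coefficients first, then $|\beta_j|$ descending,
then contribution descending. After selection, hybrid models are refit by
ridge-stabilized logistic regression ($\lambda_2 = 10^{-4}$, Newton with
step halving) to guard against complete separation in 40-patient training
splits.

## Cut-offs and thresholds

Youden cut-offs scan candidate thresholds at midpoints between
consecutive distinct sorted values, plus sentinels outside the data range;
candidates are data-independent of ordering and no observed value is ever
asserted as its own cut. $J = \text{sens} + \text{spec} - 1$ is compared
in exact integer arithmetic (common denominator $n_1 n_0$) so ties are
deterministic; ties break toward higher specificity, then the lower
threshold — the workflow favors high-specificity operating points.
"Above the cut-off" is read as strictly greater, and a value exactly at a
cut-off scores no point; this boundary convention is test-pinned.

Two threshold sources for $T$ are first-class because the source material
conflicts: a fixed text rule (0–3 points HCC, 4+ iCCA) and the
Youden-optimal threshold on training total scores. The default is
`youden_on_total`; the fixed rule is `fixed_text_rule`. The shipped
5-point variant (`prism`) carries fixed published cut-offs (ALP 439 U/L,
CA19-9 16.3 U/ml, CRP 0.87, CD9⁺ 3.2×10⁶/ml, CD81⁺ 1.06×10⁶/ml); the
hybrid Youden cut-off sets are also shipped as reference presets.

AFP runs *higher* in HCC, yet the literal additive rule still awards its
point toward iCCA above the cut-off. The package implements the rule
literally (all markers default to `above_scores_point`) and exposes a
direction-aware alternative per marker spec rather than guessing intent;
the `hybrid_fixed_afp` variant fixes AFP at the guideline 20 ng/ml.
CRP units are treated exactly as declared in the marker spec and never
converted (the source reports medians in mg/L but cut-offs in mg/dl; the
two are numerically compatible on one common scale, which is what the
generator and presets use).

## Robustness certification

* **Bootstrap** (default B = 1000): stratified within class so the AUROC
  is always defined; percentile 95% interval. Percentile rather than BCa,
  matching the reported procedure.
* **Monte Carlo perturbation** (default 500 iterations per level): every
  model-marker value is multiplied by $1 + u$, $u \sim U[-\varepsilon,
  +\varepsilon]$ independently per cell, with cut-offs and $T$ frozen; the
  uniform law reflects "values varied within predefined error ranges", and
  a truncated-Gaussian option (sd $\varepsilon/2$, truncated at
  $\pm\varepsilon$) is available. A zero-noise control row reproduces the
  deterministic evaluation exactly.
* **Repeated splits** (default 200): each split re-runs imputation,
  standardization, cross-validated L1 selection, ridge refit, and additive
  construction from scratch on its training part. Per-split seeds are
  `base_seed + index` rather than one shared stream so any split can be
  reproduced in isolation. Splits that would lose a class are re-drawn
  with an incremented sub-seed and counted; splits whose L1 support is
  empty fall back to the single best training marker, and the fallback
  count is reported. The additive-vs-hybrid comparison across splits uses
  the paired Wilcoxon signed-rank test in its tie-corrected normal
  approximation (exact enumeration is infeasible at n = 200) alongside a
  paired t test.

## Survival analysis

Patients are stratified at the within-subset median (values exactly at
the median go to the "at or below" group, per the stated convention).
Kaplan–Meier estimation and the Cox model are delegated to the survival
package (Breslow tie handling, chosen for simplicity at these cohort
sizes); the median OS is defined as the first time the KM step function
reaches 0.5 or below, not the flat-interval midpoint convention. The
weighted log-rank statistic is computed directly from the hypergeometric
O/E/V table because the Gehan–Breslow–Wilcoxon weights (total number at
risk) are not the $S(t)^\rho$ family available in `survdiff`; the plain
log-rank branch is cross-checked against `survdiff`. The median-OS-ratio
CI is a stratified bootstrap percentile interval (1000 resamples) — a
method choice, as no method is stated for the reported interval. Both the
partial-likelihood hazard ratio and the O/E-ratio approximation are
exported, labeled distinctly, because the source language conflates them.
Schoenfeld-residual diagnostics are out of scope; the proportional-hazards
assumption is noted, not tested.

## The synthetic cohort generator

No patient-level data are deposited, so the generator is the package's
study-condition bed: two classes of 25, markers log-normal
($x = e^{\mu + \sigma z}$, strictly positive, right-skewed — matching the
reported skew and the nonparametric cross-checks), missingness confined to
serology (MCAR, default rate 0.05, "limited and nonsystematic"), EV
columns complete, and censored exponential survival with a planted hazard
ratio of 2.8 for patients above the class-internal CD9⁺CD133/2⁺ median.

Calibration of the default profile:

* Class medians use the printed values where printed (AFP 16.7/3.9 ng/ml,
  ALP 271/690 U/L, CA19-9 11.4/150.8 U/ml, CRP 0.59/2.83, thrombocytes
  135/231×10³/µl). EV markers have printed fold-changes only (CD9⁺ ×2.5,
  CD63⁺ ×4.2, CD81⁺ ×12.2); HCC baselines (2.4, 1.0, 0.6 ×10⁶/ml) were
  chosen once so the shipped cut-offs fall inside the class gaps. Albumin
  medians are unprinted; 3.8/3.6 g/dl reproduces its reported AUROC 0.60.
* Log-scale dispersions are solved from the single-marker AUROCs via the
  closed form $\Phi(\Delta\mu/\sqrt{\sigma_0^2+\sigma_1^2})$ (ALP 0.79,
  CRP 1.21, thrombocytes 0.56, CD9⁺ 0.92, CD63⁺ 1.37, CD81⁺ 2.10). This
  calibration is approximate by necessity: the reported CA19-9 medians and
  AUROC are mutually inconsistent under any single log-normal (a 13-fold
  median gap with AUROC 0.65 would need $\sigma \approx 4.7$); its
  dispersion is capped at 3.5, implying AUROC ≈ 0.70.
* Survival: exponential baselines with medians 900 d (HCC) and 389.5 d
  (iCCA), administrative horizon 2000 d and random censoring rate
  2.5×10⁻⁴/d, giving censoring fractions near the reported 2/25 (iCCA)
  and 5/25 (HCC). The planted log-HR is a single scalar applied within
  both classes.
* Markers are independent by default; an optional Gaussian-copula
  correlation matrix can be supplied, since correlated features change
  L1-selection interpretation.

What the generator does *not* emulate: between-marker correlation
structure of real serum panels, assay batch effects and detection limits,
informative missingness, and non-proportional hazards. Passing tests on
synthetic cohorts therefore certify the *machinery* (correctness,
determinism, calibration recovery), not clinical performance on real
LR-M patients.

## Numerical choices and degenerate inputs

* AUROC is computed both as the trapezoid integral of the ROC curve and
  by tie-corrected pair counting (via mid-ranks); the two are identical to
  1e−12 and tested as such.
* DeLong comparisons with zero variance (e.g. self-comparison or two
  perfect models) report p = 1 with a degeneracy flag rather than NaN.
* Confusion metrics with an empty margin report the undefined metric as
  `NA`, never 0, and the χ² (Pearson, no continuity correction, df = 1)
  as `NA` when a margin is empty.
* Mann–Whitney tests are exact only for ≤ 10 untied observations per
  group, otherwise the tie-corrected normal approximation — additive
  integer scores are tie-heavy. Post-hoc power uses the noncentral-t
  formulation at the observed effect size and is descriptive only.
* A zero-variance marker is rejected by name at standardization; an
  all-identical marker is rejected at Youden derivation; degenerate
  training totals fall back to the fixed text threshold.
* Monotone Cox likelihoods (all events in one group first) are flagged
  `unbounded` rather than reported as finite estimates.

## Problem sizes used by the shipped checks

The test suite exercises the stated study conditions at sizes chosen to
keep checks sharp: generator calibration at 5 000 per class (empirical vs
closed-form AUROC within 0.01), median convergence at 50 000 per class
(the 5% band is then ≥ 2.5 standard errors even for the CA19-9 dispersion,
where 10 000 would make the band a ~1 σ coin flip), planted-marker
recovery over 200 repeated splits of a 25 + 25 cohort, hazard-ratio
recovery at 300 per arm over 100 replicates, and chance-level behavior
averaged over three independent null cohorts × 100 splits (a single
50-patient null cohort carries shared chance structure across its splits,
so averaging over cohort draws tests the property rather than one draw's
luck). End-to-end determinism is asserted on a reduced-size configuration,
identical twice-run manifests being size-independent.

## Known limitations

* The additive score is integer and unweighted by design; no nomograms or
  continuous weighted scores.
* No elastic-net or grouped penalties; no multivariable or time-varying
  Cox models; no competing risks.
* PPV/NPV are in-cohort proportions without prevalence re-weighting.
* No multiple-testing correction in the univariate panel, matching the
  original analysis.
* The generator's defaults are a calibrated emulation, not a substitute
  for external validation on real cohorts.
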