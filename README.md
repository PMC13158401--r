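# evscore

Additive scoring of serum and extracellular-vesicle (EV) markers for
differentiating hepatocellular carcinoma (HCC) from intrahepatic
cholangiocarcinoma (iCCA) in LI-RADS **LR-M** lesions.

## The problem

LR-M lesions are malignant on imaging but not specific for HCC, so current
guidelines send these patients to biopsy. A minimally invasive alternative
is to combine routine serology (AFP, albumin, ALP, CA19-9, CRP,
thrombocytes) with CD133/2⁺ small-EV subpopulations captured via their
tetraspanin co-markers (CD9⁺, CD63⁺, CD81⁺ CD133/2⁺ particles/ml) and
distill the combination into a paper-and-pencil integer score. `evscore`
implements that workflow end to end for biostatisticians developing or
stress-testing such scores:

1. **Marker prioritization** — L1-penalized logistic regression
   (coefficients β̂ minimizing `(1/n)·Σᵢ[log(1+e^{ηᵢ}) − yᵢηᵢ] + λ·Σⱼ|βⱼ|`,
   λ chosen by stratified cross-validation) merged with PCA contribution
   scores `c_m = Σ_{k≤4}|w_{mk}|` (absolute loadings over the first four
   principal components).
2. **Score construction** — per-marker cut-offs `c_m` maximizing the Youden
   index `J = sensitivity + specificity − 1`; one point per marker strictly
   above its cut-off; classify iCCA when the total reaches a threshold `T`
   (Youden-optimal on training totals, or the fixed rule `T = 4`). A
   5-point variant with fixed published cut-offs needs no computation at
   the bedside.
3. **Robustness certification** — stratified bootstrap AUROC CIs,
   Monte Carlo perturbation (`x → x·(1+u)`, `u ~ U[−ε, ε]`,
   ε ∈ {5, 10, 20}%, cut-offs frozen), and repeated 80:20 splits with the
   whole pipeline re-run from scratch per split.
4. **Exploratory survival** — Kaplan–Meier curves, log-rank and
   Gehan–Breslow–Wilcoxon tests, and a binary-covariate Cox hazard ratio
   for above-median vs at-or-below-median marker levels.
5. **Synthetic cohorts** — a calibrated log-normal generator
   (`value = exp(log_median + log_sd·z)`) with planted survival hazards and
   a closed-form single-marker AUROC
   `Φ(Δlog_median / √(σ₀² + σ₁²))`, so every stage is testable without
   patient data.

## Worked example

```r
library(evscore)

cohort <- generate_cohort(paper_like_config(seed = 7))   # 25 HCC + 25 iCCA
train  <- impute_stratified_median(cohort, "paper_faithful")

model <- build_additive_model(train, "prism", "fixed_text_rule")
print(model)
#> Additive score — variant: prism
#> marker                 units          cut-off        1 point if
#> alp_u_l                U/L            439            above
#> ca19_9_u_ml            U/ml           16.3           above
#> crp                    mg/l           0.87           above
#> cd9_cd133_2_per_ml     particles/ml   3.2e+06        above
#> cd81_cd133_2_per_ml    particles/ml   1.06e+06       above
#> Total score 0-5; classify iCCA if total >= 4 (fixed_text_rule), else HCC.

scores <- score_cohort(model, train)
auroc_value(scores$points, cohort$label)
#> [1] 0.8464

survival_stratified(cohort, "cd9_cd133_2_per_ml", label_class = 1, seed = 7)
#> Median stratification of cd9_cd133_2_per_ml in class 1: n = 25 (12 above / 13 below)
#> median OS 67.5 (above) vs 183.4 (below) days; ratio 2.72 (95% CI 0.71-71.33)
#> log-rank chi2 5.543 (p = 0.01856); Gehan chi2 4.144 (p = 0.04179)
#> Cox HR 2.955 (95% CI 1.150-7.596)
```

The scorecard is the deliverable a clinician would use: five cut-offs, one
point each, four or more points → iCCA. On this synthetic cohort the
5-point score reaches an AUROC of 0.85, and iCCA patients above the
CD9⁺CD133/2⁺ median die faster (planted hazard ratio 2.8; estimated 2.96
with a CI that covers the truth).

The full pipeline — split, prioritize, build all score variants, certify,
survival — is one call:

```r
bundle <- run_full_analysis(run_config(seed = 42))
write_report(bundle, "reports/run42")
```

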