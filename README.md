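# fetrad

Dynamic amino-acid PET radiomics for short-term survival stratification in
IDH-wildtype glioblastoma.

Even within the molecularly uniform group of IDH-wildtype glioblastomas,
some patients survive years while short-term survivors (STS, survival ≤ 12
months) die within one. Dynamic [18F]FET PET captures tracer *kinetics* —
aggressive tumors peak early and wash out, indolent tissue accumulates
steadily — that static uptake images miss. `fetrad` implements the full
analysis chain that turns a 4D dynamic PET volume into prognostic models:

* **Parametric imaging** — 20–40 min summation images normalised by a
  contralateral crescent background VOI into tumor-to-background-ratio
  (TBR) maps; voxel-wise time-to-peak (TTP) maps classifying each
  time–activity curve into six groups (< 5, 5–10, 10–15, 15–20, 20–30,
  30–40 min), with the first 2.7 min excluded and a positive late slope
  (15–40 min) forcing group 6; TBR ≥ 1.6 threshold segmentation.
* **Radiomics** — 107 IBSI-style features per image (18 first-order, 14
  shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) after isotropic
  2.03 mm resampling and fixed-bin-width discretization (0.13 for TBR,
  5 for TTP).
* **Modeling** — stratified 70/30 split, training-only standardization,
  Pearson-correlation redundancy filter (|r| > 0.99), recursive feature
  elimination with 3×5-fold cross-validated choice of k ∈ 1..15, and
  class-balanced L2-penalised logistic regression
  (weights `n/(2 n_c)`). Radiomic *signatures* — the fitted linear
  predictor `β₀ + Σ βᵢ xᵢ` — combine with the six clinical covariates
  (age, gender, KPS, WHO grade, MGMT, TERTp) into seven model variants:
  TBR, TTP, clinical, TBR-TTP, clinical-TBR, clinical-TTP,
  clinical-TBR-TTP.
* **Evaluation** — AUC, accuracy, sensitivity, specificity, PPV, NPV with
  1000-resample percentile-bootstrap 95% CIs; integrated discrimination
  improvement (IDI) between nested models; nested cross-validation (5
  outer splits) of the whole pipeline for stability.
* **Synthetic cohorts** — dynamic phantoms with gamma-variate voxel
  kinetics (analytic peak times, so TTP has a ground-truth oracle),
  clinical covariates matched to published cohort margins, and STS labels
  drawn from a calibrated logistic risk model, so the whole pipeline is
  testable without patient data. NIfTI + JSON + CSV export/import.

## Worked example

```r
library(fetrad)

cohort   <- generate_cohort(80, seed = 7)                # 80 simulated patients
features <- extract_cohort_features(cohort, kinds = "TTP")
models   <- fit_survival_models(
  features, variants = c("clinical", "TTP", "clinical-TTP"), seed = 7)

tidy(models$fits[["clinical-TTP"]])
#> # A tibble: 8 × 2
#>   term          estimate
#>   <chr>            <dbl>
#> 1 (Intercept)    -0.281
#> 2 age             0.211
#> 3 gender         -0.794
#> 4 kps            -0.0352
#> 5 who_grade       0.810
#> 6 mgmt           -1.02
#> 7 tertp           0.510
#> 8 signature_TTP   1.08

evaluate_model(models, "clinical-TTP", cohort = "test",
               n_boot = 1000, seed = 7) |> tidy()
#> # A tibble: 6 × 6
#>   variant      cohort metric      estimate ci_lower ci_upper
#> 1 clinical-TTP test   auc            0.609    0.328    0.870
#> 2 clinical-TTP test   accuracy       0.667    0.5      0.833
#> 3 clinical-TTP test   sensitivity    0.375    0        0.75
#> 4 clinical-TTP test   specificity    0.812    0.611    1
#> 5 clinical-TTP test   ppv            0.5      0        1
#> 6 clinical-TTP test   npv            0.722    0.526    0.933
```

The positive `signature_TTP` coefficient says that patients whose tumors
look kinetically aggressive on the TTP map (early peak groups) carry higher
short-term-survival risk, on top of what the six clinical covariates
explain. The IDI quantifies that added value:

```r
pc <- variant_probabilities(models, "clinical", "test")
pt <- variant_probabilities(models, "clinical-TTP", "test")
compute_idi(pc$prob, pt$prob, pc$sts_label)
#> # A tibble: 1 × 7
#>     idi     z p_value ...
#> 1 0.115 0.986   0.324
```

a 0.115 improvement in discrimination slope from adding the TTP signature
(not significant at this small n = 24 test cohort; the package's simulation
study uses 50 replicates of n = 200 to establish the effect).

`autoplot()` methods cover selection curves (`fet_selection`), metric
forests (`fet_evaluation`) and nested-CV stability (`fet_nested_cv`);
`plot_parametric_slice()` renders TBR/TTP slices with mask overlays.

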