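---
title: "Dynamic FET-PET radiomics for short-term survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic FET-PET radiomics for short-term survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetrad)
```

## The problem

Within IDH-wildtype glioblastoma — already a molecularly uniform and
aggressive entity — survival still varies widely: some patients survive
years while short-term survivors (STS, survival ≤ 12 months) die within the
first year. Dynamic amino-acid PET with [18F]FET carries kinetic information
that static uptake images do not: aggressive tumors tend to reach their
uptake peak early and wash out, while more indolent tissue accumulates
tracer steadily over the 40-minute acquisition. `fetrad` implements a
complete, testable pipeline that turns a 4D dynamic PET volume into
parametric images, extracts standardized radiomic features from them, and
combines those features with clinical covariates in class-balanced logistic
models of short-term survival.

Because clinical dynamic PET cohorts are not freely shareable, the package
pairs the analysis pipeline with a synthetic-cohort module whose ground
truth is known analytically. Every stage of the pipeline is exercised
against that ground truth; what the tests do and do not establish about
real data is discussed at the end.

## Parametric images

**TBR.** Frames covering 20–40 min post-injection are combined into a
duration-weighted summation image, and each voxel is divided by the mean
activity of a crescent-shaped background VOI in the contralateral healthy
hemisphere. Tumor segmentation thresholds the TBR image at 1.6 (inclusive),
keeping the largest 26-connected component; an all-subthreshold image is
reported as a distinct empty result rather than an error.

**TTP.** Each voxel's time–activity curve (TAC) is classified by the frame
in which it peaks, into six ordinal groups: < 5, 5–10, 10–15, 15–20, 20–30
and 30–40 min. Three conventions complete the rule, all configurable:

* frames whose *midpoints* fall before 2.7 min are excluded (early blood
  flush); the midpoint is the frame's representative time,
* an ordinary least-squares slope of frame value against frame midpoint
  over the late window (midpoints within 15–40 min) that is strictly
  positive overrides the peak-frame rule and assigns group 6,
* ties between equal maxima go to the earliest frame.

The acquisition frame schedule is configurable; the default uses 1-minute
frames to 5 min, 5-minute frames to 20 min and 10-minute frames to 40 min,
so that every TTP group boundary coincides with a frame boundary.

One inherent subtlety of frame-based TTP, visible in the tests: a voxel
whose continuous peak time lies within about one frame of a group boundary
can legitimately classify into the neighbouring group, because frame
averaging shifts the discrete argmax. The synthetic-data tests therefore
assert exact agreement away from boundaries and modal agreement overall.

## Radiomic features

Images and masks are resampled to an isotropic 2.03 mm grid (trilinear for
intensities, nearest-neighbour for the mask so it stays binary), then
discretized with a fixed bin width: gray level = `floor((x − min)/w) + 1`,
referenced to the ROI minimum. The default widths are 0.13 for TBR images
(the cohort-average interquartile range divided by four, the package also
recomputes this with `compute_bin_width_iqr4()`) and 5 for TTP images (the
shortest frame duration among the TTP categories). Applied literally to the
six ordinal groups, width 5 collapses them to two gray levels; because that
literal reading is the documented convention, it is the default, and
first-order features on the raw group values carry most of the kinetic
signal. Extraction is preceded by cropping to the mask bounding box with a
two-voxel margin, which fixes the output grid origin without affecting any
mask-local feature.

The 107 features comprise 18 first-order, 14 shape, 24 GLCM, 16 GLRLM, 16
GLSZM, 14 GLDM and 5 NGTDM features, named `<class>_<Feature>`. Texture
matrices use 13 unique 3D directions at distance 1, symmetric
probability-normalised GLCMs with feature averaging over directions, 26-
connected zones, dependence tolerance 0, and documented degenerate
conventions for single-gray-level regions (Correlation and MCC 1, Imc1/2
and Contrast 0). No image filters are applied. Every texture feature is
checked against an independent brute-force implementation (explicit voxel
loops, `rle()` on lattice lines, `igraph` components) to 1e-9 on small
regions.

**Mesh convention.** Shape features need a closed surface mesh of the
binary mask. The package uses the surface-nets (dual-contouring) algorithm:
one vertex per mixed 2×2×2 voxel block, placed at the centroid of the
block's in/out edge crossings, and one outward-wound quad per boundary
lattice edge. This mesh is closed and orientation-consistent by
construction, needs no case tables, and on a digitized sphere of radius 10
voxels reproduces sphericity 0.96 — closer to the analytic limit than a
binary-mask marching-cubes surface (0.91 in our measurements), whose area
overestimate is a known artifact of meshing binary data. Single-voxel masks
use the voxel cube as their surface. Mesh volume, surface area and the
maximum 3D/2D diameters come from the mesh; axis lengths come from the
sample covariance of masked voxel centres.

## Models

The modeling stage mirrors a standard radiomics survival-classification
design:

1. stratified 70/30 split (largest-remainder per-class allocation, so 141
   patients with 40 events split 99/42 with 28/12 events),
2. standardization (mean/population-sd) of radiomic features and of age and
   KPS, estimated on training rows only; binary covariates (gender, MGMT,
   TERTp, WHO grade 4 indicator) stay 0/1,
3. per image kind: a Pearson-correlation filter (|r| > 0.99 removes the
   second feature of the pair, in the canonical feature order), then
   recursive feature elimination under the logistic model — the feature
   with the smallest absolute standardized coefficient is dropped one at a
   time — with the candidate count k ∈ 1..15 scored by mean AUC over
   3-repeat, 5-fold stratified cross-validation (smallest k wins ties),
4. radiomic signatures: the fitted model's linear predictor, a scalar per
   patient,
5. seven model variants: TBR, TTP, clinical, TBR-TTP, clinical-TBR,
   clinical-TTP, clinical-TBR-TTP — combined variants use signatures, not
   raw features.

The classifier throughout is logistic regression with class weights
`n/(2 n_c)` (so the minority class is up-weighted and
`w₊ n₊ = w₋ n₋`), an L2 penalty of fixed unit strength on the
coefficients — the intercept is unpenalised, a documented choice — and a
damped Newton solver capped at 1000 iterations. The vanishing-penalty limit
is cross-checked against `glm()` in the tests.

## Evaluation

`evaluate_predictions()` reports AUC (midrank statistic), accuracy,
sensitivity, specificity, PPV and NPV at a probability threshold of 0.5 —
the natural cut-off under class-balanced training, and configurable — with
95% percentile-bootstrap confidence intervals from 1000 patient resamples
(single-class resamples are redrawn so the count stays exact). Integrated
discrimination improvement between nested models uses the discrimination-
slope definition with the paired-difference standard error and a two-sided
normal p value. `nested_cv()` reruns the entire pipeline (filter,
selection, fitting) inside each of five outer stratified splits and reports
per-split test AUCs, their sd and range, and the per-split selected
features — selection instability across splits is an expected finding at
these sample sizes.

## The synthetic cohort

Voxel TACs follow a normalised gamma-variate
\(c(t) = A u^{\alpha} e^{\alpha(1-u)}\), \(u = (t-t_0)/(t_p-t_0)\), which
peaks exactly at \(t_p\) with value \(A\) — chosen precisely so that TTP
classification has an analytic oracle. Frame values are exact interval
averages computed through the regularised incomplete gamma function
(`pgamma`), verified against adaptive quadrature in the tests; additive
Gaussian noise has sd proportional to the voxel amplitude (5% by default).
Count-statistics realism, attenuation, partial-volume and motion are
deliberately out of scope.

A phantom is a 32³ grid of 2 mm voxels (large enough to hold a realistic
tumor-to-grid proportion while keeping simulation studies tractable) with a
homogeneous background phenotype (A = 1, peak 15 min, shape 0.5), an
analytic crescent background VOI in the contralateral half, and a spherical
tumor whose per-voxel phenotypes create intratumoral heterogeneity:

* *aggressive*: A = 5, peaks uniform in 6–8.8 min, shape 1 — classifies
  overwhelmingly TTP group 2 with late washout,
* *indolent*: A = 3, peaks uniform in 28–36 min, shape 2 — rising late
  slope, group 6.

Cohorts draw the six clinical covariates from margins matched to the
published cohort (about 60% male, 68% WHO grade 4, 47% MGMT-methylated,
78% TERTp-mutant, age ≈ N(59, 12) truncated to 19–78, KPS mass at 70–90),
assign the aggressive phenotype with probability 0.45 independently of the
outcome, and draw the STS label from a logistic model: covariate log-odds
(0.03/year age, −0.02/point KPS, +0.5 WHO 4, −0.7 MGMT methylated, +0.6
TERTp mutation, +0.1 male — directions following the established risk
factors) plus 1.5 log-odds for the aggressive phenotype, with the intercept
calibrated by bisection (tolerance 1e-6) to a prevalence of 0.284 (forty
events per 141 patients). At these settings the *oracle* improvement in
discrimination slope between the true clinical-only and clinical+kinetic
risk models is ≈ 0.10 — the magnitude typically reported when a useful
imaging marker is added to a clinical model in this setting; the kinetic
effect was fixed by that correspondence, not by tuning to any test. Tumor radii
vary per patient (8–14 mm at the default grid) so shape and texture
features vary across the cohort.

The label never influences the phenotype; causality runs phenotype → label
only.

## Numerical and design choices

* Quartiles and percentiles everywhere use linear interpolation of order
  statistics (R type 7); this affects the IQR/4 bin width and two
  first-order features, so it is pinned and documented.
* The correlation filter needs a defined feature order for "the second
  feature is removed": first-order, shape, GLCM, GLRLM, GLSZM, GLDM,
  NGTDM, with the extraction-order names inside each class.
* A pair correlated at exactly the threshold is kept (strict inequality).
* RFE importance is the absolute standardized coefficient; one feature is
  removed per refit; warm-starting each refit from the surviving
  coefficients leaves results identical and saves most of the solver time.
* The late-slope override is applied after peak-frame classification, i.e.
  a positive 15–40 min slope always wins; this ordering is flagged for
  sensitivity analysis rather than asserted as the only reading.
* Zero-variance features are dropped with a warning at standardization and
  treated as perfectly redundant in the correlation filter.
* Degenerate inputs (empty masks, all-excluded schedules, non-positive
  background means, single-class cohorts) raise typed errors named in the
  function documentation.

## Problem sizes in the test-suite

Unit tests run on 16–24³ phantoms and ≤ 6³ texture oracles. The headline
simulation study — 50 cohorts of 200 patients at 32³ — takes roughly a
quarter of an hour on one CPU; the acceptance script's single 141-patient
cohort with both image kinds, 1000-resample bootstraps and five outer
nested-CV splits runs in about a minute.

## What passing tests do and do not show

The synthetic cohort demonstrates that the pipeline recovers a known
kinetic effect through the full chain (simulation → TTP maps → features →
selection → combined models → IDI), that no stage leaks test-cohort
information, and that every computational step matches an independent
oracle. It does not demonstrate clinical validity: gamma-variate phantoms
lack scanner noise structure, reconstruction artifacts, registration error
and biological covariance between clinical and imaging features, and the
synthetic kinetic contrast is cleaner than real intratumoral heterogeneity.
Published performance figures from real cohorts are therefore context,
not reproduction targets, for this package.
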