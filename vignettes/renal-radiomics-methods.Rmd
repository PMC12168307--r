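---
title: "Methods: renal MRI radiomics for genotype discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: renal MRI radiomics for genotype discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Beckwith–Wiedemann syndrome (BWS) is an imprinting-related overgrowth
disorder. Its molecular subtypes differ in renal risk: paternal uniparental
disomy of 11p15 and gain of imprinting at imprinting-control region 1
(together, the *renal-predisposition* class, UPD+IC1) carry elevated risk of
benign renal lesions and Wilms tumor, whereas loss of imprinting at region 2
(IC2) does not. `renalrad` implements an analysis that asks whether renal MRI
— kidney volumetry plus high-throughput texture ("radiomics") features from
T2-weighted images and ADC maps — separates the two classes.

Because no patient images are distributable, the package is built around a
**phantom generator** whose defaults encode the published cohort structure,
so every downstream stage (volumetry, feature extraction, selection,
modeling, inference) is exercised end to end on data with known ground truth.

## The phantom generator (what it emulates, what it does not)

Each subject is two axis-aligned ellipsoids ("kidneys") rasterized on a
regular grid (default 96×96×32 voxels at 0.9375×0.9375×5 mm — a 240 mm FOV at
a 256 matrix, 4 mm slices plus a 1 mm gap, so the z-spacing counts the gap).
A concentric central cavity (35% of each semi-axis, i.e. ~4.3% of the outer
volume) is excluded from the mask, standing in for the renal collecting
system: masks are parenchyma-only by construction, mirroring how the ROIs
were delineated. The outer ellipsoid is inflated by 1/(1 − 0.35³) so the
*parenchymal* volume matches the drawn target analytically; plain ellipsoids
(not general superellipsoids) are used so the analytic volume 4πabc/3 is
exact and the rasterization contract is testable to within surface-voxel
error.

Class structure, chosen once from the published cohort description and not
revisited:

* **Total volume** is linear in age, `V = a + b·age + N(0, σ)`. With ages
  uniform on integer months 6–48 (SD 12.41), the class parameters are solved
  from two published anchors: the class medians (116.18 vs 91.46 cm³,
  matched at the mean age) and the class age–volume Pearson correlations
  (0.38 vs 0.71), using `r = b·SD(age)/SD(V)`. This gives
  (a, b, σ) = (91.88, 0.90, 27.18) for UPD+IC1 and (64.46, 1.00, 12.31) for
  IC2: the predisposition class is larger but *less* age-coupled, exactly
  the qualitative structure the analysis tests.
* **Texture** is a Gaussian random field: unit-variance Gaussian-smoothed
  white noise scaled by an amplitude (45 a.u. on T2, 80 on ADC) and added to
  a base level (T2 372 a.u.; ADC drawn per subject from the class mean/SD
  1340.13 ± 67.53 vs 1343.81 ± 75.81, on the 10⁻⁶ mm²/s scale — the printed
  unit label is internally inconsistent, so the scale that matches the
  printed mean numerically is used). The correlation length is the class
  contrast dial: 2 mm (UPD+IC1, heterogeneous) vs 6 mm (IC2, smooth).
  NGTDM Busyness rises monotonically as the correlation length falls, which
  is tested.
* **Lesions**: with the class's benign-renal-anomaly probability (0.375 vs
  0.08), a hyperintense sphere (radius 3–6 mm, +8 texture-SD on T2) is
  planted inside a kidney.
* **Clinical flags** are independent Bernoulli draws at the published
  incidences (e.g. omphalocele/umbilical hernia 9/24 vs 17/25, ear
  creases/pits 4/24 vs 10/25).

Not emulated: anatomical kidney shape, MR physics (no k-space, bias field,
or partial-volume model), Wilms-tumor phenotypes, and any correlation among
clinical flags. A green recovery test therefore establishes that the
*pipeline* recovers planted volumetric/textural/clinical structure — not
that the phantom looks like a kidney.

Seeding: one master seed; per-subject and per-stage substreams are derived by
an integer hash (`derive_seed`), all below 2³¹, so a run is reproducible
bit-for-bit within this implementation.

## Volumetry

Volume is voxel count × voxel volume per kidney, total = left + right
exactly; mean T2/ADC are over raw masked voxels (the published summary table
reports native statistics). The packaged normative table (7 half-year age
bands, 6–48 months, population mean ± 2 SD) drives nephromegaly
classification with *strict* inequalities — a volume exactly at the upper
limit is "within", since nephromegaly means strictly exceeding the limit. Band
membership is half-open: age 48 is out of range because the last band ends
at 47.99.

## Filter bank (15 derived image types)

original; Laplacian-of-Gaussian at σ = 1 and 2 mm (the two scales named in
the published feature list), computed as reflect-boundary Gaussian smoothing
followed by the physical-units Laplacian scaled by σ²; 8 subbands of a
single-level *undecimated* coiflet-1 wavelet decomposition (periodic
boundary, filters scaled by 1/√2 so the 8-band transform is a tight frame:
energies add to the input energy and the adjoint reconstructs exactly); and
four noise-type images — shot (Poisson) noise, binomial blur ((1,2,1)/4 per
axis, periodic so the mean is preserved exactly), speckle, and additive
Gaussian noise. The published text names only four filter kinds "such as";
speckle and additive-Gaussian are the package's choice to reach the stated
15 types, and the composition is config-visible. "Short noise" is read as
shot noise, following the selected-feature table. Boundary rules are a
deliberate mix: reflect for smoothing (no edge ringing inside near-boundary
masks), periodic where an exactness contract (mean preservation, tight
frame) is wanted.

## Feature bank (1246)

16 shape features on the original-geometry mask plus 82 intensity features
per image type (18 first-order + 20 GLCM + 14 GLRLM + 13 GLSZM + 12 GLDM +
5 NGTDM) × 15 types = 1246 — the published bank width; the exact
composition of the proprietary bank is not recoverable, so this manifest is
a reconstruction constrained by the printed total and the named features,
which are all included and oracle-tested.

Numerical conventions, fixed so downstream selection never sees NaN:

* Discretization: fixed bin count 32 over the masked range per image type
  (filtered images are signed, so fixed-count is well-defined); a constant
  region collapses to one level.
* GLCM: 13 Chebyshev-distance-1 directions, counts pooled over directions,
  symmetrized, normalized to sum 1. On a single-voxel or constant region the
  diagonal-concentration measures (Correlation, Id/Idm/Idmn/Idn) take 1 and
  dispersion measures take 0.
* GLDM: α = 0, 26-neighbourhood; the dependence index j counts qualifying
  neighbours and lives in matrix column j+1 (j = 0…26). Feature sums with j
  in a denominator skip the j = 0 column.
* GLSZM zones are 26-connected equal-level components; GLRLM runs are summed
  over the 13 directions (RunPercentage is normalized by 13·Np); NGTDM
  Busyness is 0 when its denominator vanishes, Coarseness is capped at 10⁶.
* Shape: surface area by exposed-face counting; maximum 2D/3D diameters are
  exact via per-slice convex hulls (every 3D hull vertex lies on its slice's
  2D hull); axis lengths are 4√λ from the coordinate covariance eigenvalues.

Extraction crops to the mask bounding box (margin 4 voxels), which makes
intensity features exactly translation invariant and cost proportional to
the VOI.

## Selection cascade and voting

Per training fold: z-normalize (sample SD, fitted on the training split
only — the source text is silent on leakage control, so the conservative
choice is made), then keep features passing (1) point-biserial correlation
p < 0.05 — the stated "correlation coefficient (P 0.05)" is read as a
label-association screen because the criterion is a p-value, not an |r|
cutoff; (2) univariate logistic Wald p < 0.10, with a likelihood-ratio
fallback under separation; (3) multivariate logistic at p < 0.05, realized as
backward stepwise elimination on drop-one likelihood-ratio p-values — a
single joint fit of hundreds of collinear radiomic survivors separates
perfectly and every Wald p degenerates to 1, selecting nothing, whereas the
LR statistic is asymptotically equivalent and stays defined under
separation; candidates are first capped at the floor(n/5) best by univariate
p, greedily decorrelated at |r| < 0.9; (4) LASSO at penalty strength
0.05 — "alpha-value 0.05" is read as the L1 penalty magnitude, the
conventional meaning in radiomics platform reports, and is config-exposed.
Voting counts are selection frequencies across the 5 stratified folds; the
final single-sequence set needs ≥ 4 of 5 votes (every published
single-model feature had count 4 or 5). The combined model is the union of
the two single-sequence finals, with combined counts recomputed by re-voting
on the pooled table.

## Model grid

8 preprocessors (identity, z-score, min-max, robust-quantile scaling, each
with and without PCA retaining 95% variance — the preprocessors are unnamed
in the source, so this bank is a documented reconstruction) × 13 classifiers
= 104 pipelines per model. The 8 named classifier families (logistic
regression, random forest, GBDT, KNN, PLS-DA, QDA, SGD, SVM) are joined by 5
conventional additions (decision tree, extra trees, AdaBoost, Gaussian naive
Bayes, LDA) to reach the stated 13. No tree/kernel package exists in the
dependency closure, so the trees, ensembles, KNN, PLS, SGD and linear SVM
(Pegasos) are implemented in the package with fixed hyperparameters (no
inner tuning; none is described at the source). All pipelines share one
stratified fold partition so later AUC comparisons are paired; sensitivity
and specificity are reported at the per-fold Youden-optimal threshold (the
threshold rule is unstated at the source); the mean-AUC CI is a percentile
bootstrap over fold AUCs. Ties in best-model selection break by mean
accuracy, then enumeration order.

## Inference

The DeLong paired-AUC test uses the placement-value (structural components)
estimator with midrank ties; p is two-sided normal, clamped to 1 when the
variance of the difference is 0 and the AUCs are equal. Contingency tables
use Pearson chi-square *without* continuity correction when all expected
counts are ≥ 5, else two-sided Fisher — calibrated against the published
worked examples (χ² = 4.574 → p ≈ 0.032; χ² = 6.121 → p ≈ 0.013), which only
the uncorrected statistic reproduces. One published row (ear creases/pits,
4/24 vs 10/25, printed p = 0.048) is *not* reproducible by uncorrected or
corrected chi-square or Fisher (all give ~0.07–0.11); it is documented here
rather than silently matched. Group comparisons gate on Shapiro–Wilk at
0.05 per group (the normal/non-normal dichotomy is stated but its test is
not): both normal → Welch t, else Mann–Whitney U (normal approximation,
midranks, tie and continuity correction).

## Limitations

* The phantom's texture dial is a stationary Gaussian field; real
  parenchymal heterogeneity is non-stationary and anisotropic.
* Patient-level headline AUCs (0.837/0.882/0.954) and fold-wise DeLong
  p-values are not reproducible without the clinical images; the contract is
  procedural fidelity plus recovery of planted synthetic structure.
* The acceptance recovery cohort runs at a coarser grid (64×64×24 at
  1.875×1.875×5 mm) than the scanner default purely for runtime; class
  models are untouched.
* The 82-feature intensity list and the preprocessor bank are principled
  reconstructions; alternative compositions of the same width would be
  equally consistent with the published totals.
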