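---
title: "First-order texture analysis of thyroid CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-order texture analysis of thyroid CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

Normal thyroid tissue absorbs iodine and therefore images homogeneously on
non-enhanced CT, at roughly 90–120 HU. Nodular tissue (goiter, thyroiditis,
adenoma, carcinoma) loses that capability: its mean attenuation falls below
about 70 HU and its spatial structure becomes heterogeneous — necrotic and
haemorrhagic regions, water-like cysts near 0–10 HU, calcifications far
above 120 HU. `thyrotex` quantifies that difference and turns it into a
classifier:

1. **ROI ingestion** (`load_ct_image()`, `load_mask()`, `apply_mask()`):
   single-frame CT DICOM slices are converted to Hounsfield units via
   `HU = stored * RescaleSlope + RescaleIntercept`; a binary mask (DICOM,
   PNG or NIfTI; nonzero = inside) selects the thyroid region. The ROI is
   the *set* of masked pixel values. Although the delineation procedure is
   often described as multiplying image by mask, a literal product would
   drag the outside zeros into every statistic; all sums here run over the
   masked set only.
2. **Denoising filter bank** (`build_filter_bank()`): 3×3 moving-average,
   median and adaptive Wiener filters. Filtering runs on the *full* image
   before masking, so no artificial values are blended across the ROI
   boundary. Borders use edge replication. The Wiener variant is the
   local-statistics (Lee) filter with the noise power estimated as the
   mean of all local variances — the default behaviour of the standard
   toolbox implementations; we always estimate rather than accept a
   manual noise figure.
3. **First-order features** (`extract_first_order()`): entropy
   `e = -Σ p(l) log2 p(l)`, uniformity `u = Σ p(l)^2`, mean `m`, sample
   standard deviation `sd` (n−1 denominator), bias-corrected skewness `s`
   and bias-corrected *excess* kurtosis `k` (the `−3(n−1)²/((n−2)(n−3))`
   reference term included; no alternative convention is offered). A
   13-feature GLCM baseline (`glcm_features()`) is provided for
   comparison.
4. **Normalization and screening** (`fit_min_max()`, `apply_min_max()`,
   `compare_groups_ttest()`): per-feature min–max scaling to [0, 1];
   pooled two-sample t-tests per feature.
5. **Feature selection** (`sffs_select()`): sequential floating forward
   selection with a kNN leave-one-out accuracy criterion, run on a
   stratified selection half and re-scored on the validation half without
   refitting the subset.
6. **Classification** (`train_svm()`, `train_lda()`, `train_ann()`,
   `loocv_evaluate()`): soft-margin RBF-SVM with a cross-validated grid
   search, Fisher LDA, and a one-hidden-layer (10 tanh units, linear
   output) neural network; leave-one-out evaluation with the whole
   training procedure nested inside each fold.
7. **Evaluation** (`compute_metrics()`, `roc_auc()`): sensitivity,
   specificity, PPV, NPV, accuracy from the confusion counts (positive
   class = nodule), plus a threshold-sweep ROC whose trapezoidal AUC
   equals the tie-aware Mann–Whitney statistic.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| filter window | 3×3 px | matches the scale of photon noise; larger windows erase regional texture |
| histogram bins `n_bins` | 256 | 8-bit quantization, the de facto standard for first-order radiomics; `range_policy` is the ROI's own min–max, with a fixed HU range selectable |
| GLCM `levels`, offsets | 64; distance 1 at 0°/45°/90°/135°, symmetric | conventional Haralick setup |
| kNN criterion `k` | 1 | the selection criterion is only specified as "k-nearest neighbour"; k = 1 is the strictest and cheapest choice, configurable |
| SVM grid | C ∈ 2^−5…2^15, γ ∈ 2^−15…2^3, powers of 4; 5 folds | standard coarse RBF grid; pipeline-scale runs use a reduced grid (see below) |
| split fraction | 0.5 stratified | "two groups" with no stated ratio |
| label encoding | nodule = +1, normal = −1 | sensitivity is defined on nodules |
| min ROI size | 16 px | kurtosis needs n ≥ 4; 16 px guards against meaningless histograms |

Tie-breaking is fully pinned down because SFFS is sensitive to it:
distance ties prefer the lower sample index, vote ties the normal class,
criterion ties among candidate features the earlier feature order, and
criterion ties among subsets the smaller subset.

### Decisions where the design was genuinely open

* **HU rescale before extraction**: whether features should be computed on
  rescaled HU or raw stored values cannot be settled from the source
  material; `rescale_policy` defaults to HU (`"hu"`), with `"raw"` and
  `"strict"` available. For the linear slope-1 dialect the choice only
  shifts the mean feature.
* **t-test variant**: pooled ("Student's") by default, Welch selectable.
  The reported `F` is the pooled-test `t²`, recorded in the output as an
  interpretation rather than asserted as the historical computation.
* **Normalization scope**: leakage-safe by default — min–max parameters
  are fitted inside every LOOCV fold. `paper_mode = TRUE` fits them once
  on the full matrix, mirroring a global-normalization protocol.
* **Grid-search nesting**: nested inside LOOCV by default; a global grid
  search would be optimistic on correlated folds.
* **LOOCV unit**: per image by default (matching the historical protocol)
  although patients contribute 2–3 images; `grouping = "patient"` is
  offered because image-level LOOCV on correlated images is optimistic.
* **ANN**: hand-written tanh-hidden/linear-output network trained by BFGS
  on the exact backpropagation gradient, because that is the stated
  architecture (tansig/purelin); initialization is seeded, the iteration
  cap is 500, and non-convergence keeps the best-so-far weights with a
  warning.
* **GLCM sum variance**: defined as the dispersion of the level-sum
  distribution about the *sum average* (the classical formula's reference
  to sum entropy is widely regarded as a typo). "Contrast" and "inertia"
  share one formula and are reported under both names to preserve the
  13-name feature list.

### Numerical conventions

Degenerate inputs are flagged, not fatal: a constant ROI has `e = 0`,
`u = 1`, `sd = 0` and its shape statistics are *defined* as 0 with a
degeneracy flag (classifiers need finite values); constant feature
columns normalize to 0; metrics with zero denominators are reported as 0
with a flag; out-of-range test values are clipped to [0, 1] and counted.
ROC ties contribute 1/2 (midrank). Report tables round half-up at 3
decimals; full precision is kept in memory.

## The phantom generator

`generate_phantom()` builds a 64×64 slice with an elliptical ROI
(semi-axes ~7–12 × 9–14 px, ≈ 350 masked pixels) in a muscle-like 50 HU
background. Normal phantoms draw a mean from U[90, 120] HU with texture
amplitude 8 HU; nodules draw U[30, 70] HU with amplitude 25 HU, a
water-like cyst (10 HU) with probability 0.35 and one to three ~300 HU
calcification specks with probability 0.3. Photon noise is additive
pixel-iid Gaussian (sd 5 HU) and pixel values are rounded to integer HU,
as CT stored values are.

Two modeling choices deserve emphasis:

* **Tissue texture is a smooth random field** (correlation length ≈ 2 px),
  not pixel-iid noise: heterogeneity from necrosis, haemorrhage and
  calcification is regional, while photon noise is pixel-scale. This
  spatial-scale separation is precisely what a 3×3 filter exploits, and a
  pixel-iid texture model would make denoising indistinguishable from
  texture removal.
* **Texture amplitudes carry a per-patient lognormal jitter** (sdlog 0.4),
  so weakly-heterogeneous nodules overlap strongly-textured normals in
  any single feature. Without it every single feature would separate the
  classes perfectly and the classifier stages would be untestable.
* **The background is soft tissue (50 HU), not air**: the thyroid sits in
  the neck surrounded by muscle and vessels. Because filtering precedes
  masking, an air background would leak ≈ −1000 HU into boundary ROI
  pixels of every filtered group — an artifact clinical slices do not
  have. Air remains selectable via `background_hu = -1000`.

Patients are synthesized as groups of 2–3 images sharing their drawn mean
and texture amplitude, enabling patient-level cross-validation.

### What the phantoms do and do not show

Phantom classes are anchored to the reported HU ranges, and the test
suite verifies the direction of the group differences (nodules: higher
entropy and standard deviation, lower uniformity and mean) and that the
full pipeline separates the classes at study-level accuracy. The phantoms
do **not** emulate anatomy (lobe shape, tracheal neighbourhood, partial
volume at the capsule), scanner physics (beam hardening, correlated
noise, reconstruction kernels) or the biological diversity of real
nodules; passing the phantom suite therefore demonstrates that the
*implementation* is sound, not that the method generalizes clinically.

One negative finding is worth recording. The filter-bank robustness
experiment (`filter_noise_experiment()`: add sd-15 HU noise, compare
unfiltered vs median-filtered texture features under nested SVM LOOCV)
shows at most a 1–3 sample accuracy change on 142 phantoms, and the
median-filtered arm does not reliably out-score the noisy unfiltered arm.
At ≈ 350 px per ROI the per-sample moment estimates are statistically
stable (the standard error of `sd` is well under 1 HU), so iid noise
*shifts* each class's feature distribution — `sd → sqrt(sd² + 15²)` —
rather than corrupting individual samples; min–max normalization absorbs
much of the shift, and the residual error is dominated by phantoms whose
texture amplitude is intrinsically ambiguous, which no denoising can fix.
The filters do restore per-feature separation (the normal-class `sd`
returns to its clean value under the median filter), which is visible in
the feature-level diagnostics; an accuracy-level rescue would require
smaller ROIs or noise large relative to the class gap. The experiment —
deliberately run on the texture features only, since the mean is
invariant to zero-mean noise — remains in the acceptance suite as a
documented red check rather than being weakened.

## Problem sizes

The shipped experiments use 150 normal + 134 nodule phantoms (mirroring
the historical cohort), 64×64 slices, a reduced SVM grid
(C ∈ 4^0…4^3, γ ∈ 4^−3…4^0, 3 folds) inside LOOCV, and 75 + 67 phantoms
for the filter experiment; the full coarse grid is the package default
for standalone training. Oracle-based tests run on 100 random ROIs and
exhaustive feature-subset searches up to 8 features / 30 samples.

## Known limitations

* Single-frame, single-ROI processing; 3-D volumes and automatic
  segmentation are out of scope.
* The DICOM codec covers the uncompressed little-endian dialects and the
  CT tags this pipeline needs; it is not a general DICOM implementation.
* No multiple-testing correction across feature t-tests (raw p-values
  only), and no AUC confidence intervals.
* The ANN comparator is a minimal backpropagation network; it is present
  for comparison, not tuned for performance.
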