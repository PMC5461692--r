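# thyrotex

Computer-aided detection of thyroid nodules in non-enhanced CT slices from
first-order texture statistics of a delineated region of interest.

Normal thyroid tissue takes up iodine and images homogeneously at roughly
90–120 HU; nodular tissue does not (mean attenuation typically below
70 HU) and is spatially heterogeneous — necrosis, haemorrhage, water-like
cysts, calcifications above 120 HU. `thyrotex` turns that contrast into a
classification pipeline for radiological research use:

* masked-ROI ingestion from single-frame CT DICOM (`HU = stored × slope +
  intercept`) with DICOM/PNG/NIfTI binary masks;
* a 3×3 denoising filter bank — moving average, median, adaptive (Lee)
  Wiener — applied to the full image before masking;
* the six first-order features per ROI and filter group

  | feature | definition |
  |---|---|
  | entropy | `e = −Σ p(l) log₂ p(l)` |
  | uniformity | `u = Σ p(l)²` |
  | mean intensity | `m = (1/n) Σ a(x,y)` |
  | standard deviation | `sd = [Σ (a − ā)² / (n−1)]^{1/2}` |
  | excess kurtosis | `k = n(n+1)/((n−1)(n−2)(n−3)) · Σ((a−ā)/sd)⁴ − 3(n−1)²/((n−2)(n−3))` |
  | skewness | `s = n/((n−1)(n−2)) · Σ((a−ā)/sd)³` |

  over the histogram probabilities `p(l)` and masked HU values `a(x,y)`,
  plus a 13-feature GLCM (Haralick) baseline;
* min–max normalization `Y = (X − min)/(max − min)`, pooled t-tests per
  feature, a stratified selection/validation split;
* sequential floating forward selection (SFFS) with a kNN leave-one-out
  accuracy criterion;
* RBF-kernel soft-margin SVM (cross-validated grid search over C and γ),
  Fisher LDA, and a one-hidden-layer tanh/linear neural network, all
  evaluated by leave-one-out cross-validation with normalization and
  hyperparameter search nested inside every fold;
* sensitivity, specificity, PPV, NPV, accuracy (positive class = nodule)
  and threshold-sweep ROC/AUC;
* a seeded synthetic phantom generator so the whole pipeline is testable
  without clinical data.

## Worked example

Generate a small phantom cohort, extract features under all four filter
groups, and run the selection + SVM pipeline:

```r
library(thyrotex)

ds <- generate_dataset(n_normal = 30, n_nodule = 26, seed = 7)
ft <- extract_feature_table(ds$samples)

# direction of the entropy difference on unfiltered features
fm <- build_feature_matrix(ft$features_by_group, "non-filter",
                           ft$labels, ft$sample_ids, ft$patient_ids)
nm <- apply_min_max(fm, fit_min_max(fm))
t_e <- compare_groups_ttest(nm, "e4")

res <- run_experiment(ft, subsets = list("A6, M6, W6" = c("A6", "M6", "W6")),
                      classifiers = "svm",
                      svm_cfg = svm_config(grid_c = 4^(0:3),
                                           grid_gamma = 4^(-3:0),
                                           cv_folds = 3L),
                      seed = 7)
res[["A6, M6, W6"]]$report
```

This prints:

```
entropy: nodule 0.672 +- 0.160 vs normal 0.248 +- 0.116 (p = 4.6e-16)
selected: sd2
ACC 0.946  SEN 0.885  SPC 1.000  PPV 1.000  NPV 0.909  AUC 1.000
```

Nodule phantoms carry markedly higher normalized entropy than normal ones
(heterogeneous vs homogeneous tissue), SFFS picked a single
median-filtered feature (`sd2` — the standard deviation in filter group 2)
on the selection half, and the nested leave-one-out SVM classifies 53 of
the 56 held-out phantoms correctly; the three misses are nodules whose
texture amplitude falls inside the normal range, which is exactly the
overlap the generator is designed to produce. Feature-column names follow
the group-suffix convention: suffix 1 = Wiener, 2 = median, 3 = average,
4 = unfiltered, so `e1` is the entropy under the Wiener filter.

A thin CLI over the same functions lives at `inst/cli/thyrotex.R`
(`simulate`, `extract`, `run-all` subcommands).

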