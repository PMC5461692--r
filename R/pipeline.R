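# End-to-end orchestration: simulate -> extract -> select -> train ->
# evaluate -> report.
#
# Feature tables carry one row per ROI with the 6 first-order features of
# every requested filter group (suffix 1 = wiener, 2 = median, 3 = average,
# 4 = non-filter). Experiments are nested and leakage-safe by default:
# min-max normalization and the SVM hyperparameter grid are refit inside
# every leave-one-out fold; `paper_mode = TRUE` instead fits the
# normalization once on the full matrix, mirroring a global-normalization
# protocol.

ALL_GROUPS <- c("W6", "M6", "A6", "non-filter")

group_filter_spec <- function(tag, window = 3L) {
  switch(tag,
         "W6" = filter_spec("wiener", window),
         "M6" = filter_spec("median", window),
         "A6" = filter_spec("average", window),
         "non-filter" = filter_spec("none"))
}

#' Extract per-group first-order features for a set of ROI samples
#'
#' Each image is filtered with every requested filter (on the full image),
#' then restricted to its mask; the six first-order features are computed
#' per filter group.
#'
#' @param samples list of `list(image =, mask =, label =)` entries, e.g.
#'   from [generate_dataset()] or loaded from a manifest.
#' @param groups filter group tags, default all four.
#' @param window filter window (odd, default 3).
#' @param n_bins,range_policy histogram settings, see
#'   [histogram_probabilities()].
#' @return list: `features_by_group` (named list of samples x 6 matrices),
#'   `labels` (+1/-1), `sample_ids`, `patient_ids`.
#' @export
extract_feature_table <- function(samples, groups = ALL_GROUPS, window = 3L,
                                  n_bins = 256L,
                                  range_policy = "roi_minmax") {
  stopifnot(length(samples) >= 1L)
  specs <- lapply(groups, group_filter_spec, window = window)
  per_group <- lapply(groups, function(g)
    matrix(NA_real_, length(samples), 6L,
           dimnames = list(NULL, FIRST_ORDER_NAMES)))
  names(per_group) <- groups
  labels <- integer(length(samples))
  ids <- character(length(samples)); pids <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    bank <- build_filter_bank(s$image, specs)
    for (gi in seq_along(groups)) {
      roi <- apply_mask(bank[[gi]], s$mask, label = s$label)
      hist <- histogram_probabilities(roi, n_bins = n_bins,
                                      range_policy = range_policy)
      per_group[[gi]][i, ] <- extract_first_order(roi, hist)
    }
    labels[i] <- if (s$label == "nodule") 1L else -1L
    ids[i] <- s$sample_id %||% s$image$source_id %||% paste0("s", i)
    pids[i] <- s$patient_id %||% ids[i]
  }
  list(features_by_group = per_group, labels = labels,
       sample_ids = ids, patient_ids = pids)
}

load_manifest_samples <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    image <- load_ct_image(manifest$image_path[i])
    list(image = image,
         mask = load_mask(manifest$mask_path[i], image),
         label = manifest$label[i],
         sample_id = if ("sample_id" %in% names(manifest))
           manifest$sample_id[i] else basename(manifest$image_path[i]),
         patient_id = manifest$patient_id[i])
  })
}

#' Extract features for every ROI in a manifest and write a CSV table
#'
#' Rows that fail to load or extract are logged as warnings and skipped;
#' the run continues.
#'
#' @param manifest_path ROI manifest CSV (see [read_roi_manifest()]).
#' @param out_csv output CSV path.
#' @param groups,window,n_bins,range_policy see [extract_feature_table()].
#' @return the feature table data.frame, invisibly (also written to
#'   `out_csv`).
#' @export
run_extract <- function(manifest_path, out_csv, groups = ALL_GROUPS,
                        window = 3L, n_bins = 256L,
                        range_policy = "roi_minmax") {
  manifest <- read_roi_manifest(manifest_path)
  samples <- list()
  kept <- integer(0)
  for (i in seq_len(nrow(manifest))) {
    s <- tryCatch({
      image <- load_ct_image(manifest$image_path[i])
      list(image = image,
           mask = load_mask(manifest$mask_path[i], image),
           label = manifest$label[i],
           sample_id = if ("sample_id" %in% names(manifest))
             manifest$sample_id[i] else basename(manifest$image_path[i]),
           patient_id = manifest$patient_id[i])
    }, error = function(e) {
      warnf("skipping sample %d (%s): %s", i,
            basename(manifest$image_path[i]), conditionMessage(e))
      NULL
    })
    if (!is.null(s)) {
      samples[[length(samples) + 1L]] <- s
      kept <- c(kept, i)
    }
  }
  if (length(samples) == 0L) stopf("no readable samples in manifest")
  ft <- extract_feature_table(samples, groups = groups, window = window,
                              n_bins = n_bins, range_policy = range_policy)
  blocks <- lapply(groups, function(g) {
    b <- ft$features_by_group[[g]]
    colnames(b) <- group_feature_names(g)
    b
  })
  out <- data.frame(sample_id = ft$sample_ids, patient_id = ft$patient_ids,
                    label = manifest$label[kept],
                    do.call(cbind, blocks), check.names = FALSE)
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}

#' Read a feature table CSV back into per-group matrices
#'
#' @param path CSV written by [run_extract()].
#' @return same structure as [extract_feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  groups <- ALL_GROUPS[vapply(ALL_GROUPS, function(g)
    all(group_feature_names(g) %in% names(df)), logical(1))]
  per_group <- lapply(groups, function(g) {
    b <- as.matrix(df[, group_feature_names(g)])
    colnames(b) <- FIRST_ORDER_NAMES
    b
  })
  names(per_group) <- groups
  list(features_by_group = per_group,
       labels = ifelse(df$label == "nodule", 1L, -1L),
       sample_ids = df$sample_id, patient_ids = df$patient_id)
}

#' Run a feature-subset / selection / classification experiment
#'
#' For each configured group subset: assemble the feature matrix, optionally
#' run SFFS on a stratified selection split (normalized within that split)
#' and re-score the chosen subset on the validation split without
#' refitting, then evaluate each classifier by leave-one-out
#' cross-validation with nested normalization (and, for the SVM, a nested
#' hyperparameter grid search), and compute the confusion metrics and
#' ROC/AUC.
#'
#' @param feature_table output of [extract_feature_table()] /
#'   [read_feature_table()].
#' @param subsets list of character vectors of group tags; names become
#'   result names (defaults to tags joined by ", ", the table row
#'   convention).
#' @param classifiers character vector among `"svm"`, `"lda"`, `"ann"`.
#' @param sffs run feature selection (default TRUE).
#' @param sffs_k kNN neighbours for the selection criterion.
#' @param split_fraction selection-group fraction for the SFFS split.
#' @param svm_cfg an [svm_config()] for the nested grid search.
#' @param grouping LOOCV unit, `"image"` or `"patient"`.
#' @param paper_mode fit min-max once on the full matrix instead of per
#'   fold.
#' @param seed master seed.
#' @param outdir optional report directory for [render_reports()].
#' @return named list of results: per subset x classifier, a list with
#'   `report` (metrics), `roc`, `selected`, `validation_criterion`, `loocv`.
#' @export
run_experiment <- function(feature_table,
                           subsets = list(c("A6", "M6", "W6")),
                           classifiers = "svm",
                           sffs = TRUE, sffs_k = 1L, split_fraction = 0.5,
                           svm_cfg = svm_config(), grouping = "image",
                           paper_mode = FALSE, seed = 1L, outdir = NULL) {
  if (is.null(names(subsets)))
    names(subsets) <- vapply(subsets, paste, "", collapse = ", ")
  results <- list()
  seeds <- derive_seeds(seed, 2L * length(subsets))
  for (si in seq_along(subsets)) {
    tags <- subsets[[si]]
    if (!all(tags %in% ALL_GROUPS)) stopf("invalid subset names")
    fm <- build_feature_matrix(feature_table$features_by_group, tags,
                               feature_table$labels,
                               feature_table$sample_ids,
                               feature_table$patient_ids)
    selected <- fm$feature_names
    validation_criterion <- NA_real_
    if (isTRUE(sffs)) {
      halves <- split_selection_validation(fm, split_fraction, seeds[si])
      sel_norm <- apply_min_max(halves$selection, fit_min_max(halves$selection))
      sres <- sffs_select(sel_norm, k = sffs_k)
      selected <- sres$selected
      val_norm <- apply_min_max(halves$validation,
                                fit_min_max(halves$validation))
      validation_criterion <-
        knn_loocv_accuracy(val_norm, selected, k = sffs_k)
    }
    fm_sel <- subset_features(fm, features = selected)
    if (paper_mode)
      fm_sel <- apply_min_max(fm_sel, fit_min_max(fm_sel))
    for (cl in classifiers) {
      cv <- loocv_evaluate(fm_sel,
                           spec = list(kind = cl, config = svm_cfg),
                           grouping = grouping,
                           seed = seeds[length(subsets) + si],
                           normalize = !paper_mode)
      roc <- roc_auc(cv$scores, cv$truth)
      rep <- compute_metrics(confusion_counts(cv$truth, cv$predicted),
                             auc = roc$auc)
      nm <- if (length(classifiers) > 1L)
        paste0(names(subsets)[si], " [", cl, "]") else names(subsets)[si]
      results[[nm]] <- list(report = rep, roc = roc, selected = selected,
                            validation_criterion = validation_criterion,
                            loocv = cv)
    }
  }
  if (!is.null(outdir)) render_reports(results, outdir)
  results
}

#' Filter-bank noise-robustness experiment
#'
#' Generates a phantom dataset, measures leave-one-out classification
#' accuracy on the unfiltered texture features, then adds pixel-iid
#' Gaussian noise to the same phantoms and measures accuracy again on (a)
#' unfiltered and (b) median-filtered features. The feature set is the
#' texture subset (entropy, uniformity, sd, kurtosis, skewness): mean
#' intensity is essentially invariant to zero-mean noise — it reflects
#' iodine uptake rather than heterogeneity — so including it would mask
#' the effect the denoising filters are there to rescue.
#'
#' @param n_normal,n_nodule per-class phantom counts.
#' @param extra_noise_sd added noise sd in HU (default 15).
#' @param seed master seed.
#' @param svm_cfg grid for the nested LOOCV SVM.
#' @param config template [phantom_config()].
#' @return list: `acc_clean`, `acc_noisy`, `acc_median`, `recovery`
#'   (fraction of the lost accuracy recovered by the median filter).
#' @export
filter_noise_experiment <- function(n_normal = 75L, n_nodule = 67L,
                                    extra_noise_sd = 15, seed = 1L,
                                    svm_cfg = svm_config(
                                      grid_c = 4^(0:3), grid_gamma = 4^(-3:0),
                                      cv_folds = 3L),
                                    config = phantom_config()) {
  seeds <- derive_seeds(seed, 4L)
  ds <- generate_dataset(n_normal, n_nodule, seed = seeds[1L], config = config)
  noisy <- ds
  noisy$samples <- with_seed(seeds[2L], lapply(ds$samples, function(s) {
    px <- round(s$image$pixels +
                  stats::rnorm(length(s$image$pixels), 0, extra_noise_sd))
    s$image <- ct_image(px, pixel_spacing_mm = s$image$pixel_spacing_mm,
                        source_id = s$image$source_id, hu_range = NULL)
    s
  }))
  texture <- setdiff(FIRST_ORDER_NAMES, "m")
  acc_of <- function(samples, group, fold_seed) {
    ft <- extract_feature_table(samples, groups = group)
    fm <- build_feature_matrix(ft$features_by_group, group, ft$labels,
                               ft$sample_ids, ft$patient_ids)
    keep <- paste0(texture, GROUP_INDEX[[group]])
    fm <- subset_features(fm, features = keep)
    cv <- loocv_evaluate(fm, spec = list(kind = "svm", config = svm_cfg),
                         seed = fold_seed)
    mean(cv$predicted == cv$truth)
  }
  acc_clean <- acc_of(ds$samples, "non-filter", seeds[3L])
  acc_noisy <- acc_of(noisy$samples, "non-filter", seeds[4L])
  acc_median <- acc_of(noisy$samples, "M6", seeds[4L])
  loss <- acc_clean - acc_noisy
  list(acc_clean = acc_clean, acc_noisy = acc_noisy,
       acc_median = acc_median,
       recovery = if (loss > 0) (acc_median - acc_noisy) / loss else NA_real_)
}
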