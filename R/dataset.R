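# Sample-by-feature matrix assembly across filter groups, min-max
# normalization to [0, 1], per-feature two-sample t-tests and the
# selection/validation split.
#
# Column naming follows the group-suffix convention: e1,u1,m1,sd1,k1,s1 for
# group 1 (wiener), suffix 2 = median, 3 = average, 4 = non-filter, so "e1"
# is the entropy under the Wiener filter and "k3" the kurtosis under the
# average filter.

GROUP_INDEX <- c("W6" = 1L, "M6" = 2L, "A6" = 3L, "non-filter" = 4L)
# map the single-image filter tags onto subset group tags
TAG_TO_GROUP <- c("W" = "W6", "M" = "M6", "A" = "A6",
                  "non-filter" = "non-filter")

group_feature_names <- function(group_tag) {
  paste0(FIRST_ORDER_NAMES, GROUP_INDEX[[group_tag]])
}

#' Construct a feature matrix object
#'
#' @param values numeric matrix, samples x features, no missing values.
#' @param labels integer vector in `{+1, -1}` (+1 = nodule, -1 = normal).
#' @param sample_ids,patient_ids character vectors (optional; defaults
#'   generated).
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, sample_ids = NULL,
                           patient_ids = NULL) {
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  if (any(!is.finite(values))) stopf("feature matrix contains missing values")
  if (!all(labels %in% c(-1L, 1L)))
    stopf("labels must be +1 (nodule) or -1 (normal)")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(patient_ids)) patient_ids <- sample_ids
  structure(
    list(values = values, feature_names = colnames(values),
         labels = as.integer(labels), sample_ids = as.character(sample_ids),
         patient_ids = as.character(patient_ids)),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features (%d nodule / %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == 1L), sum(x$labels == -1L)))
  invisible(x)
}

#' Subset a feature matrix by rows and/or feature names
#'
#' @param fm a `feature_matrix`.
#' @param rows integer/logical row index (default all).
#' @param features character vector of feature names (default all).
#' @return a `feature_matrix`.
#' @export
subset_features <- function(fm, rows = NULL, features = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(fm$values))
  if (is.null(features)) features <- fm$feature_names
  missing <- setdiff(features, fm$feature_names)
  if (length(missing))
    stopf("unknown features: %s", paste(missing, collapse = ", "))
  feature_matrix(fm$values[rows, features, drop = FALSE],
                 fm$labels[rows], fm$sample_ids[rows], fm$patient_ids[rows])
}

#' Assemble the feature matrix for a subset of filter groups
#'
#' @param features_by_group named list mapping group tags (`"W6"`, `"M6"`,
#'   `"A6"`, `"non-filter"`) to samples x 6 matrices of first-order features
#'   in `e, u, m, sd, k, s` order (as produced by [extract_feature_table()]).
#' @param subset_spec character vector of group tags, in order; columns are
#'   concatenated group by group and suffixed with the group index.
#' @param labels,sample_ids,patient_ids as in [feature_matrix()].
#' @return a `feature_matrix` with `6 * length(subset_spec)` columns.
#' @export
build_feature_matrix <- function(features_by_group, subset_spec, labels,
                                 sample_ids = NULL, patient_ids = NULL) {
  missing <- setdiff(subset_spec, names(features_by_group))
  if (length(missing))
    stopf("feature group(s) not computed: %s", paste(missing, collapse = ", "))
  blocks <- lapply(subset_spec, function(tag) {
    b <- features_by_group[[tag]]
    stopifnot(ncol(b) == 6L)
    colnames(b) <- group_feature_names(tag)
    b
  })
  feature_matrix(do.call(cbind, blocks), labels, sample_ids, patient_ids)
}

#' Fit per-feature min-max normalization parameters
#'
#' @param fm a `feature_matrix` with at least 2 samples.
#' @return a `minmax_params` list: `min`, `max`, `degenerate` (max == min).
#' @export
fit_min_max <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) < 2L) stopf("need >= 2 samples to fit normalization")
  mins <- apply(fm$values, 2L, min)
  maxs <- apply(fm$values, 2L, max)
  structure(list(min = mins, max = maxs, degenerate = maxs <= mins,
                 feature_names = fm$feature_names),
            class = "minmax_params")
}

#' Apply min-max normalization
#'
#' `Y = (X - min) / (max - min)` per feature. Degenerate (constant) columns
#' map to 0; values beyond the fitted range (e.g. test samples outside the
#' training min/max) are clipped to `[0, 1]` and counted in the `n_clipped`
#' attribute.
#'
#' @param fm a `feature_matrix`.
#' @param params a `minmax_params` fitted on compatible columns.
#' @return a normalized `feature_matrix`.
#' @export
apply_min_max <- function(fm, params) {
  stopifnot(inherits(params, "minmax_params"))
  if (!identical(fm$feature_names, params$feature_names))
    stopf("feature columns do not match normalization parameters")
  span <- params$max - params$min
  span[params$degenerate] <- 1  # avoid 0/0; result forced to 0 below
  y <- sweep(sweep(fm$values, 2L, params$min, "-"), 2L, span, "/")
  y[, params$degenerate] <- 0
  n_clipped <- sum(y < 0 | y > 1)
  y[y < 0] <- 0; y[y > 1] <- 1
  out <- feature_matrix(y, fm$labels, fm$sample_ids, fm$patient_ids)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Two-sample t-test comparing one feature between classes
#'
#' Independent-samples Student's t-test (pooled variance by default;
#' `welch = TRUE` for unequal variances) of the named feature between the
#' nodule (+1) and normal (-1) groups. The reported `f` is the pooled-test
#' F = t^2 (an interpretation, recorded in the output).
#'
#' @param fm a `feature_matrix` with both classes present (>= 2 per class).
#' @param feature feature name.
#' @param welch use the Welch (unequal-variance) test.
#' @return list: `t`, `p`, `f`, `df`, per-class `mean` and `sd`.
#' @export
compare_groups_ttest <- function(fm, feature, welch = FALSE) {
  x <- fm$values[, feature]
  g1 <- x[fm$labels == 1L]; g0 <- x[fm$labels == -1L]
  if (length(g1) < 2L || length(g0) < 2L)
    stopf("need >= 2 samples per class for the t-test")
  tt <- tryCatch(stats::t.test(g1, g0, var.equal = !welch),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # both groups constant: infinite separation if means differ
    diff <- mean(g1) - mean(g0)
    tt <- list(statistic = c(t = if (diff > 0) Inf else if (diff < 0) -Inf else 0),
               p.value = if (diff != 0) 0 else 1,
               parameter = c(df = length(g1) + length(g0) - 2))
  }
  list(feature = feature,
       t = unname(tt$statistic), p = tt$p.value,
       f = unname(tt$statistic)^2, f_definition = "t_squared_pooled",
       df = unname(tt$parameter),
       mean = c(nodule = mean(g1), normal = mean(g0)),
       sd = c(nodule = stats::sd(g1), normal = stats::sd(g0)))
}

#' Stratified selection/validation split
#'
#' Randomly divides the samples into a selection group and a validation
#' group, stratified by class, reproducibly for a given seed.
#'
#' @param fm a `feature_matrix`.
#' @param fraction selection-group fraction in (0, 1), default 0.5.
#' @param seed integer seed.
#' @return list of two `feature_matrix` objects: `selection`, `validation`.
#' @export
split_selection_validation <- function(fm, fraction = 0.5, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) stopf("fraction must be in (0, 1)")
  sel <- with_seed(seed, {
    idx <- logical(nrow(fm$values))
    for (cls in c(1L, -1L)) {
      rows <- which(fm$labels == cls)
      n_take <- round(length(rows) * fraction)
      if (n_take < 1L || n_take >= length(rows))
        stopf("class %+d too small to stratify at fraction %g", cls, fraction)
      idx[sample(rows, n_take)] <- TRUE
    }
    idx
  })
  list(selection = subset_features(fm, rows = which(sel)),
       validation = subset_features(fm, rows = which(!sel)))
}
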