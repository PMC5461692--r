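# Confusion-matrix indices, ROC/AUC and report rendering.
#
# The positive class is the nodule (+1). Any index whose denominator is
# zero is reported as 0 with its flag set, so degenerate classifiers (e.g.
# an all-negative predictor) produce finite, comparable rows.

#' Tally a confusion matrix
#'
#' @param truth,predicted equal-length vectors with labels in `{+1, -1}`.
#' @return a `confusion_matrix` list: `n_tp`, `n_tn`, `n_fp`, `n_fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stopf("truth and predicted lengths differ")
  if (length(truth) < 1L) stopf("need at least one prediction")
  if (!all(c(truth, predicted) %in% c(-1L, 1L)))
    stopf("labels must be +1 or -1")
  structure(
    list(n_tp = sum(truth == 1L & predicted == 1L),
         n_tn = sum(truth == -1L & predicted == -1L),
         n_fp = sum(truth == -1L & predicted == 1L),
         n_fn = sum(truth == 1L & predicted == -1L)),
    class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#'
#' @param n_tp,n_tn,n_fp,n_fn non-negative integers, total >= 1.
#' @return a `confusion_matrix`.
#' @export
confusion_matrix <- function(n_tp, n_tn, n_fp, n_fn) {
  counts <- c(n_tp, n_tn, n_fp, n_fn)
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  structure(list(n_tp = n_tp, n_tn = n_tn, n_fp = n_fp, n_fn = n_fn),
            class = "confusion_matrix")
}

safe_ratio <- function(num, den) if (den > 0) num / den else 0

#' Sensitivity, specificity, PPV, NPV and accuracy from a confusion matrix
#'
#' `SEN = TP/(TP+FN)`, `SPC = TN/(TN+FP)`, `PPV = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)`, `ACC = (TP+TN)/total`. Zero-denominator indices are
#' reported as 0 and listed in `zero_denominator_flags`.
#'
#' @param cm a `confusion_matrix`.
#' @param auc optional AUC to carry along.
#' @return a `metrics_report` list: `sen`, `spc`, `ppv`, `npv`, `acc`,
#'   `auc`, `zero_denominator_flags`.
#' @export
compute_metrics <- function(cm, auc = NA_real_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  dens <- c(sen = cm$n_tp + cm$n_fn, spc = cm$n_tn + cm$n_fp,
            ppv = cm$n_tp + cm$n_fp, npv = cm$n_tn + cm$n_fn)
  structure(
    list(sen = safe_ratio(cm$n_tp, unname(dens["sen"])),
         spc = safe_ratio(cm$n_tn, unname(dens["spc"])),
         ppv = safe_ratio(cm$n_tp, unname(dens["ppv"])),
         npv = safe_ratio(cm$n_tn, unname(dens["npv"])),
         acc = (cm$n_tp + cm$n_tn) /
           (cm$n_tp + cm$n_tn + cm$n_fp + cm$n_fn),
         auc = auc,
         zero_denominator_flags = names(dens)[dens == 0],
         confusion = cm),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.3f  SEN %.3f  SPC %.3f  PPV %.3f  NPV %.3f  AUC %s\n",
              x$acc, x$sen, x$spc, x$ppv, x$npv,
              ifelse(is.na(x$auc), "-", sprintf("%.3f", x$auc))))
  if (length(x$zero_denominator_flags))
    cat("zero-denominator:", paste(x$zero_denominator_flags, collapse = ", "),
        "\n")
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' The curve sweeps all unique score thresholds (predict positive when
#' `score >= threshold`); the AUC is the trapezoidal area, which equals the
#' normalized Mann-Whitney U statistic with ties contributing 1/2.
#'
#' @param scores finite numeric scores, higher = more nodule-like.
#' @param truth labels in `{+1, -1}`; both classes must be present.
#' @return list with `curve` (data.frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == -1L)
  if (n_pos == 0L || n_neg == 0L)
    stopf("both classes must be present for a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1L), numeric(1)) / n_pos
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == -1L), numeric(1)) / n_neg
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

round_half_up <- function(x, digits = 3L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

metrics_row <- function(name, report, extra = list()) {
  row <- data.frame(
    ACC = round_half_up(report$acc), SEN = round_half_up(report$sen),
    SPC = round_half_up(report$spc), PPV = round_half_up(report$ppv),
    NPV = round_half_up(report$npv),
    AUC = if (is.na(report$auc)) NA_real_ else round_half_up(report$auc))
  cbind(data.frame(name = name, stringsAsFactors = FALSE),
        as.data.frame(extra, stringsAsFactors = FALSE), row)
}

#' Render result tables to CSV
#'
#' Writes the evaluated configurations as CSV reports: one metrics row per
#' configuration (named by its feature subset or classifier, with the
#' selected-feature string when selection ran) and the confusion counts of
#' each configuration. Values are rendered at 3 decimals (half-up); full
#' precision stays in the in-memory result objects.
#'
#' @param results non-empty named list; each element needs a
#'   `metrics_report` under `$report` and may carry `$selected`.
#' @param dir output directory (created if missing).
#' @return paths of the files written, invisibly.
#' @export
render_reports <- function(results, dir) {
  if (length(results) == 0L) stopf("nothing to report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    metrics_row(nm, r$report,
                extra = list(selected_features =
                               paste(r$selected %||% "", collapse = ", ")))
  })
  summary_path <- file.path(dir, "results.csv")
  utils::write.csv(do.call(rbind, rows), summary_path, row.names = FALSE)
  conf <- do.call(rbind, lapply(names(results), function(nm) {
    cm <- results[[nm]]$report$confusion
    data.frame(name = nm, n_tp = cm$n_tp, n_fn = cm$n_fn,
               n_fp = cm$n_fp, n_tn = cm$n_tn)
  }))
  conf_path <- file.path(dir, "confusion.csv")
  utils::write.csv(conf, conf_path, row.names = FALSE)
  roc_paths <- character(0)
  for (nm in names(results)) {
    r <- results[[nm]]
    if (!is.null(r$roc)) {
      p <- file.path(dir, paste0("roc_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv"))
      utils::write.csv(r$roc$curve, p, row.names = FALSE)
      roc_paths <- c(roc_paths, p)
    }
  }
  invisible(c(summary_path, conf_path, roc_paths))
}
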