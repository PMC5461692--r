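# Sequential floating forward selection (SFFS) with a k-nearest-neighbour
# leave-one-out accuracy criterion.
#
# SFFS results are sensitive to tie handling, so the rules are fixed:
# distance ties -> lower sample index; vote ties -> the normal (-1) class;
# criterion ties between candidate features -> earlier feature order;
# criterion ties between subsets -> the smaller subset.

#' Leave-one-out k-nearest-neighbour accuracy of a feature subset
#'
#' Each sample is classified by the majority vote of its `k` nearest
#' neighbours (Euclidean distance on the subset columns) among all other
#' samples; returns the fraction classified correctly.
#'
#' @param fm a `feature_matrix`.
#' @param features non-empty character vector of feature names.
#' @param k number of neighbours, `1 <= k < n_samples` (default 1).
#' @return accuracy in `[0, 1]`.
#' @export
knn_loocv_accuracy <- function(fm, features, k = 1L) {
  if (length(features) == 0L) stopf("feature subset must be non-empty")
  n <- nrow(fm$values)
  if (k < 1L || k >= n) stopf("k must satisfy 1 <= k < n_samples")
  x <- fm$values[, features, drop = FALSE]
  d <- as.matrix(stats::dist(x))
  correct <- 0L
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    nb <- order(di)[seq_len(k)]  # order() is stable: ties -> lower index
    vote <- sum(fm$labels[nb])
    pred <- if (vote > 0L) 1L else -1L  # vote tie -> normal class
    if (pred == fm$labels[i]) correct <- correct + 1L
  }
  correct / n
}

#' Sequential floating forward selection
#'
#' Classic SFFS: each forward step adds the not-yet-selected feature that
#' maximizes the criterion and is accepted only if it strictly improves the
#' best criterion recorded for the new subset size; after each accepted
#' forward step, floating backward steps remove any feature whose removal
#' strictly improves the best criterion recorded for the smaller size.
#' Terminates when the size reaches `max_features` or no forward step
#' improves. The result is the best subset over all sizes (criterion ties
#' broken by smaller subset, then by feature order).
#'
#' @param fm a `feature_matrix` with >= 2 features and both classes.
#' @param k neighbours for the kNN criterion (default 1).
#' @param max_features size cap (default: all features).
#' @param criterion optional function `(fm, features) -> [0,1]`; defaults to
#'   [knn_loocv_accuracy()] with the given `k`.
#' @return an `sffs_result`: `selected` (in inclusion order),
#'   `best_criterion`, `criterion_trace` (data.frame of accepted steps:
#'   kind, feature, size, criterion).
#' @export
sffs_select <- function(fm, k = 1L, max_features = NULL, criterion = NULL) {
  feats <- fm$feature_names
  p <- length(feats)
  if (p < 2L) stopf("need >= 2 features for selection")
  if (length(unique(fm$labels)) < 2L) stopf("both classes must be present")
  if (is.null(max_features)) max_features <- p
  max_features <- min(max_features, p)
  crit <- if (is.null(criterion))
    function(fm, f) knn_loocv_accuracy(fm, f, k = k)
  else criterion

  best_by_size <- rep(-Inf, max_features)   # best criterion seen per size
  best_set_by_size <- vector("list", max_features)
  trace <- list()
  record <- function(kind, feature, set, value) {
    trace[[length(trace) + 1L]] <<- data.frame(
      kind = kind, feature = feature, size = length(set), criterion = value,
      stringsAsFactors = FALSE)
    sz <- length(set)
    if (value > best_by_size[sz]) {
      best_by_size[sz] <<- value
      best_set_by_size[[sz]] <<- set
    }
  }

  current <- character(0)
  repeat {
    if (length(current) >= max_features) break
    # forward: best candidate among remaining features (ties -> feature order)
    remaining <- setdiff(feats, current)
    vals <- vapply(remaining, function(f) crit(fm, c(current, f)), numeric(1))
    f_best <- remaining[which.max(vals)]
    v_best <- max(vals)
    if (v_best <= best_by_size[length(current) + 1L]) break  # no improvement
    current <- c(current, f_best)
    record("add", f_best, current, v_best)

    # floating backward: remove while strictly improving the smaller size
    while (length(current) > 2L) {
      vals_r <- vapply(seq_along(current),
                       function(idx) crit(fm, current[-idx]), numeric(1))
      idx_best <- which.max(vals_r)
      if (vals_r[idx_best] > best_by_size[length(current) - 1L]) {
        removed <- current[idx_best]
        current <- current[-idx_best]
        record("remove", removed, current, vals_r[idx_best])
      } else break
    }
  }

  sizes <- which(is.finite(best_by_size))
  if (length(sizes) == 0L) stopf("selection failed: no subset evaluated")
  # best over all sizes; ties -> smaller subset (earlier size index)
  best_size <- sizes[which.max(best_by_size[sizes])]
  structure(
    list(selected = best_set_by_size[[best_size]],
         best_criterion = best_by_size[best_size],
         criterion_trace = do.call(rbind, trace)),
    class = "sffs_result")
}

#' @export
print.sffs_result <- function(x, ...) {
  cat(sprintf("<sffs_result> %d features, criterion %.4f: %s\n",
              length(x$selected), x$best_criterion,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
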