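# Classifiers: soft-margin RBF-SVM with cross-validated grid search
# (via the e1071 dual solver), linear discriminant analysis (MASS, with a
# ridge-Fisher fallback), and a one-hidden-layer neural network with tanh
# hidden units and a linear output, trained by gradient-based
# backpropagation (BFGS on the analytic gradient).
#
# Every trained model obeys one score contract: higher score = more
# nodule-like, labels = sign(score) with 0 mapped to the normal class.

#' RBF-SVM configuration
#'
#' @param grid_c candidate penalty parameters C (> 0); default powers of 4
#'   from 2^-5 to 2^15.
#' @param grid_gamma candidate RBF widths (> 0); default powers of 4 from
#'   2^-15 to 2^3.
#' @param cv_folds stratified cross-validation folds for the grid search
#'   (>= 2, default 5).
#' @return an `svm_config` list.
#' @export
svm_config <- function(grid_c = 2^seq(-5, 15, by = 2),
                       grid_gamma = 2^seq(-15, 3, by = 2),
                       cv_folds = 5L) {
  stopifnot(length(grid_c) > 0, all(grid_c > 0),
            length(grid_gamma) > 0, all(grid_gamma > 0), cv_folds >= 2L)
  structure(list(grid_c = sort(grid_c), grid_gamma = sort(grid_gamma),
                 cv_folds = as.integer(cv_folds)),
            class = "svm_config")
}

check_trainable <- function(fm) {
  if (any(!is.finite(fm$values))) stopf("non-finite feature values")
  if (length(unique(fm$labels)) < 2L)
    stopf("both classes must be present for training")
}

stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      rows <- which(labels == cls)
      fold[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
    }
    fold
  })
}

svm_fit_raw <- function(x, y, cost, gamma) {
  e1071::svm(x = x, y = factor(y, levels = c(-1L, 1L)), scale = FALSE,
             kernel = "radial", cost = cost, gamma = gamma)
}

# decision values oriented so that higher = nodule (+1)
svm_scores <- function(model, x) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  cn <- colnames(dv)[1L]
  # column name "A/B": positive decision value favours class A
  if (identical(strsplit(cn, "/")[[1L]][1L], "1")) dv[, 1L] else -dv[, 1L]
}

#' Train a soft-margin RBF-kernel SVM with grid-searched hyperparameters
#'
#' For every `(C, gamma)` pair in the grid, stratified `cv_folds`-fold
#' cross-validation accuracy is computed; the best pair (ties broken toward
#' smaller C, then smaller gamma) is refit on all input data with the
#' soft-margin RBF-SVM dual solver.
#'
#' @param fm a `feature_matrix` (typically min-max normalized).
#' @param config an [svm_config()].
#' @param seed integer seed for the fold assignment.
#' @return a `thyro_classifier` of kind `"svm"`; `$cv_table` holds the grid
#'   search accuracies, `$cost`/`$gamma` the winners.
#' @export
train_svm <- function(fm, config = svm_config(), seed = 1L) {
  check_trainable(fm)
  x <- fm$values; y <- fm$labels
  fold <- stratified_folds(y, config$cv_folds, seed)
  grid <- expand.grid(gamma = config$grid_gamma, cost = config$grid_c)
  acc <- vapply(seq_len(nrow(grid)), function(gi) {
    hits <- 0L
    for (f in seq_len(config$cv_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      m <- svm_fit_raw(x[tr, , drop = FALSE], y[tr],
                       grid$cost[gi], grid$gamma[gi])
      pred <- as.integer(as.character(
        stats::predict(m, x[!tr, , drop = FALSE])))
      hits <- hits + sum(pred == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  # grid ordered by (cost, gamma) ascending; first strict max wins the ties
  best <- which.max(acc)
  model <- svm_fit_raw(x, y, grid$cost[best], grid$gamma[best])
  structure(
    list(kind = "svm", model = model, cost = grid$cost[best],
         gamma = grid$gamma[best],
         cv_table = cbind(grid, accuracy = acc),
         feature_names = fm$feature_names),
    class = "thyro_classifier")
}

#' Train a linear discriminant analysis classifier
#'
#' Fisher discriminant via `MASS::lda`; the score is the projection onto the
#' discriminant direction, oriented so that higher = nodule. If the pooled
#' within-class covariance is (near-)singular, a ridge-regularized Fisher
#' discriminant is fitted instead and the applied epsilon recorded.
#'
#' @param fm a `feature_matrix`.
#' @param ridge_fallback allow the ridge fallback (default TRUE).
#' @return a `thyro_classifier` of kind `"lda"`.
#' @export
train_lda <- function(fm, ridge_fallback = TRUE) {
  check_trainable(fm)
  x <- fm$values; y <- fm$labels
  fit <- tryCatch(
    suppressWarnings(MASS::lda(x, grouping = factor(y, levels = c(-1L, 1L)))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    w <- fit$scaling[, 1L]
    mu1 <- colMeans(x[y == 1L, , drop = FALSE])
    mu0 <- colMeans(x[y == -1L, , drop = FALSE])
    if (sum((mu1 - mu0) * w) < 0) w <- -w
    # threshold from the class-mean projections, prior-corrected as in LDA
    s1 <- sum(mu1 * w); s0 <- sum(mu0 * w)
    pr <- fit$prior
    thr <- (s1 + s0) / 2 - log(pr["1"] / pr["-1"]) / (s1 - s0)
    if (!is.finite(thr)) thr <- (s1 + s0) / 2
    return(structure(list(kind = "lda", w = w, threshold = unname(thr),
                          ridge = 0, feature_names = fm$feature_names),
                     class = "thyro_classifier"))
  }
  if (!ridge_fallback) stopf("singular within-class covariance in LDA")
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  mu0 <- colMeans(x[y == -1L, , drop = FALSE])
  n1 <- sum(y == 1L); n0 <- sum(y == -1L)
  xc <- x
  xc[y == 1L, ] <- sweep(x[y == 1L, , drop = FALSE], 2L, mu1)
  xc[y == -1L, ] <- sweep(x[y == -1L, , drop = FALSE], 2L, mu0)
  S <- crossprod(xc) / (n1 + n0 - 2)
  eps <- 1e-6 * max(mean(diag(S)), 1e-12)
  w <- solve(S + diag(eps, ncol(x)), mu1 - mu0)
  structure(list(kind = "lda", w = w,
                 threshold = sum((mu1 + mu0) / 2 * w), ridge = eps,
                 feature_names = fm$feature_names),
            class = "thyro_classifier")
}

#' Train a one-hidden-layer neural network
#'
#' Feed-forward network: inputs -> `hidden` tanh (tansig) units -> one
#' linear (purelin) output, trained by backpropagation (BFGS on the exact
#' gradient of the mean squared error against targets +1/-1, with a small
#' L2 weight penalty). Initialization is seeded, so training is
#' deterministic for a given seed.
#'
#' @param fm a `feature_matrix`.
#' @param seed integer seed for weight initialization.
#' @param hidden hidden-layer width (default 10).
#' @param maxit iteration cap (default 500); non-convergence within the cap
#'   raises a warning and keeps the best-so-far weights.
#' @param decay L2 penalty (default 1e-4).
#' @return a `thyro_classifier` of kind `"ann"`.
#' @export
train_ann <- function(fm, seed = 1L, hidden = 10L, maxit = 500L,
                      decay = 1e-4) {
  check_trainable(fm)
  x <- fm$values; y <- as.numeric(fm$labels)
  n <- nrow(x); p <- ncol(x); h <- as.integer(hidden)
  n_par <- p * h + h + h + 1L
  unpack <- function(th) list(
    W1 = matrix(th[seq_len(p * h)], p, h),
    b1 = th[p * h + seq_len(h)],
    W2 = th[p * h + h + seq_len(h)],
    b2 = th[n_par])
  fwd <- function(pr) {
    z <- tanh(sweep(x %*% pr$W1, 2L, pr$b1, "+"))
    list(z = z, out = as.vector(z %*% pr$W2 + pr$b2))
  }
  obj <- function(th) {
    pr <- unpack(th)
    f <- fwd(pr)
    mean((f$out - y)^2) + decay * sum(th^2)
  }
  grad <- function(th) {
    pr <- unpack(th)
    f <- fwd(pr)
    r <- 2 * (f$out - y) / n           # d loss / d out
    gW2 <- as.vector(crossprod(f$z, r))
    gb2 <- sum(r)
    dz <- (r %o% pr$W2) * (1 - f$z^2)  # back through tanh
    gW1 <- crossprod(x, dz)
    gb1 <- colSums(dz)
    c(as.vector(gW1), gb1, gW2, gb2) + 2 * decay * th
  }
  th0 <- with_seed(seed, stats::runif(n_par, -0.5, 0.5) / sqrt(p + 1))
  fit <- stats::optim(th0, obj, grad, method = "BFGS",
                      control = list(maxit = as.integer(maxit)))
  if (fit$convergence != 0L)
    warnf("ANN training did not converge within %d iterations; keeping best-so-far weights",
          maxit)
  structure(list(kind = "ann", params = unpack(fit$par), hidden = h,
                 loss = fit$value, feature_names = fm$feature_names),
            class = "thyro_classifier")
}

#' Predict labels and nodule scores
#'
#' @param object a `thyro_classifier`.
#' @param newdata a `feature_matrix` or bare numeric matrix with the
#'   training feature columns.
#' @param ... unused.
#' @return list with `labels` (+1/-1; a score of exactly 0 maps to -1) and
#'   real-valued `scores` (higher = more nodule-like, usable for ROC).
#' @export
predict.thyro_classifier <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  stopifnot(is.matrix(x))
  if (ncol(x) != length(object$feature_names))
    stopf("feature count %d does not match training (%d)",
          ncol(x), length(object$feature_names))
  if (nrow(x) == 0L)
    return(list(labels = integer(0), scores = numeric(0)))
  scores <- switch(
    object$kind,
    svm = as.numeric(svm_scores(object$model, x)),
    lda = as.numeric(x %*% object$w) - object$threshold,
    ann = {
      z <- tanh(sweep(x %*% object$params$W1, 2L, object$params$b1, "+"))
      as.vector(z %*% object$params$W2 + object$params$b2)
    })
  list(labels = ifelse(scores > 0, 1L, -1L), scores = scores)
}

classifier_trainer <- function(spec) {
  kind <- spec$kind
  switch(kind,
         svm = function(fm, seed) train_svm(
           fm, config = spec$config %||% svm_config(), seed = seed),
         lda = function(fm, seed) train_lda(fm),
         ann = function(fm, seed) suppressWarnings(train_ann(
           fm, seed = seed, hidden = spec$hidden %||% 10L)),
         stopf("unknown classifier kind '%s'", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-out evaluation with a fully nested training procedure
#'
#' For each held-out unit (one image, or all images of one patient), the
#' complete training procedure — min-max normalization fit, hyperparameter
#' grid search, final fit — runs on the remaining units only, so the
#' held-out unit never influences normalization or hyperparameter choice.
#'
#' @param fm an UNnormalized `feature_matrix` (normalization is fitted
#'   inside each fold).
#' @param spec classifier spec: `list(kind = "svm"|"lda"|"ann", config =,
#'   hidden =)`.
#' @param grouping `"image"` (default; one sample per fold) or `"patient"`
#'   (all images of a patient held out together).
#' @param seed integer seed (per-fold seeds are derived from it).
#' @param normalize fit min-max inside each fold (default TRUE).
#' @return list: `truth`, `predicted`, `scores`, aligned with the input
#'   sample order.
#' @export
loocv_evaluate <- function(fm, spec = list(kind = "svm"),
                           grouping = c("image", "patient"), seed = 1L,
                           normalize = TRUE) {
  grouping <- match.arg(grouping)
  n <- nrow(fm$values)
  if (n < 3L) stopf("need >= 3 samples for leave-one-out evaluation")
  units <- if (grouping == "patient") {
    if (is.null(fm$patient_ids)) stopf("patient grouping needs patient_ids")
    fm$patient_ids
  } else seq_len(n)
  uniq <- unique(units)
  trainer <- classifier_trainer(spec)
  fold_seeds <- derive_seeds(seed, length(uniq))
  pred <- integer(n); scores <- numeric(n)
  for (ui in seq_along(uniq)) {
    hold <- units == uniq[ui]
    tr_fm <- subset_features(fm, rows = which(!hold))
    te_fm <- subset_features(fm, rows = which(hold))
    if (normalize) {
      pars <- fit_min_max(tr_fm)
      tr_fm <- apply_min_max(tr_fm, pars)
      te_fm <- apply_min_max(te_fm, pars)
    }
    model <- trainer(tr_fm, fold_seeds[ui])
    out <- stats::predict(model, te_fm)
    pred[hold] <- out$labels
    scores[hold] <- out$scores
  }
  list(truth = fm$labels, predicted = pred, scores = scores)
}
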