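# SVM / LDA / ANN classifiers and leave-one-out evaluation.

small_grid <- svm_config(grid_c = 4^(0:3), grid_gamma = 4^(-2:1),
                         cv_folds = 3L)

test_that("the RBF-SVM separates linear blobs and survives contradictions", {
  fm <- make_gauss_fm(15, 2, seed = 71, sep = 6)
  m <- train_svm(fm, small_grid, seed = 1)
  pred <- predict(m, fm)
  expect_equal(mean(pred$labels == fm$labels), 1.0)
  # duplicated contradictory points: irreducible error, but no crash
  xdup <- rbind(matrix(0, 6, 2), matrix(0, 6, 2)) + 0
  contradictory <- feature_matrix(xdup, c(rep(1L, 6), rep(-1L, 6)))
  m2 <- train_svm(contradictory, small_grid, seed = 1)
  p2 <- predict(m2, contradictory)
  expect_lte(mean(p2$labels == contradictory$labels), 0.5 + 1e-9)
})

test_that("SVM decision values equal the kernel-expansion oracle", {
  fm <- make_gauss_fm(12, 3, seed = 72, sep = 2)
  m <- train_svm(fm, small_grid, seed = 2)
  sv <- m$model$SV
  co <- m$model$coefs[, 1]
  rho <- m$model$rho
  xt <- fm$values[1:5, , drop = FALSE]
  kexp <- sapply(seq_len(nrow(xt)), function(i) {
    kk <- exp(-m$gamma * colSums((t(sv) - xt[i, ])^2))
    sum(co * kk) - rho
  })
  # orientation: e1071's raw decision value favours its first factor level
  got <- predict(m, xt)$scores
  expect_equal(abs(got), abs(kexp), tolerance = 1e-6)
  expect_equal(mean(sign(got) == sign(kexp)) %in% c(0, 1), TRUE)
})

test_that("the grid-search winner dominates every other grid point", {
  fm <- make_gauss_fm(12, 3, seed = 73, sep = 1.5)
  m <- train_svm(fm, small_grid, seed = 3)
  tab <- m$cv_table
  win <- tab$accuracy[tab$cost == m$cost & tab$gamma == m$gamma]
  expect_true(all(win >= tab$accuracy))
  # ties break toward smaller C, then smaller gamma
  top <- tab[tab$accuracy == max(tab$accuracy), ]
  expect_equal(m$cost, min(top$cost))
  expect_equal(m$gamma, min(top$gamma[top$cost == min(top$cost)]))
})

test_that("SVM training is invariant to sample order", {
  fm <- make_gauss_fm(10, 3, seed = 74, sep = 2)
  set.seed(74); perm <- sample(nrow(fm$values))
  fmp <- subset_features(fm, rows = perm)
  m1 <- train_svm(fm, small_grid, seed = 4)
  # re-derive folds on permuted data would differ; fix hyperparameters to
  # isolate the decision function itself
  cfg <- svm_config(grid_c = m1$cost, grid_gamma = m1$gamma, cv_folds = 3L)
  m2 <- train_svm(fmp, cfg, seed = 4)
  probe <- matrix(rnorm(15, 0, 2), 5, 3)
  # agreement up to the dual solver's working tolerance
  expect_equal(predict(m1, probe)$scores, predict(m2, probe)$scores,
               tolerance = 5e-3)
})

test_that("LDA recovers the analytic discriminant direction for spherical classes", {
  set.seed(75)
  n <- 500
  mu <- c(2, -1, 0.5)
  x1 <- matrix(rnorm(n * 3), n, 3) + rep(mu, each = n)
  x0 <- matrix(rnorm(n * 3), n, 3)
  fm <- feature_matrix(rbind(x1, x0), c(rep(1L, n), rep(-1L, n)))
  m <- train_lda(fm)
  cosine <- sum(m$w * mu) / sqrt(sum(m$w^2) * sum(mu^2))
  expect_gt(cosine, 0.99)
})

test_that("LDA degenerates gracefully and uses the midpoint threshold in 1-D", {
  set.seed(76)
  x <- matrix(rnorm(80, 0, 1), 40, 2)
  fm <- feature_matrix(x, rep(c(1L, -1L), 20))  # identical class means
  m <- train_lda(fm)
  acc <- mean(predict(m, fm)$labels == fm$labels)
  expect_lt(abs(acc - 0.5), 0.2)
  x1 <- rnorm(200, 2, 1); x0 <- rnorm(200, -2, 1)
  fm1 <- feature_matrix(cbind(f = c(x1, x0)), c(rep(1L, 200), rep(-1L, 200)))
  m1 <- train_lda(fm1)
  crossing <- as.numeric(m1$threshold / m1$w)  # score = w*x - threshold = 0
  expect_equal(crossing, (mean(x1) + mean(x0)) / 2, tolerance = 0.05)
  # constant column triggers the ridge fallback rather than an error
  fmc <- feature_matrix(cbind(f = c(x1, x0), z = rep(1, 400)),
                        c(rep(1L, 200), rep(-1L, 200)))
  mc <- train_lda(fmc)
  expect_gt(mc$ridge, 0)
  expect_gt(mean(predict(mc, fmc)$labels == fmc$labels), 0.9)
})

test_that("the tanh ANN fits separable data, is seed-deterministic and handles constants", {
  fm <- make_gauss_fm(20, 2, seed = 77, sep = 4)
  m <- train_ann(fm, seed = 5)
  expect_gte(mean(predict(m, fm)$labels == fm$labels), 0.95)
  m2 <- train_ann(fm, seed = 5)
  expect_identical(m$params, m2$params)
  m3 <- suppressWarnings(train_ann(fm, seed = 6))  # cap hit is fine here
  expect_false(identical(m$params, m3$params))
  const <- feature_matrix(matrix(0, 10, 2), rep(c(1L, -1L), 5))
  mc <- suppressWarnings(train_ann(const, seed = 7, maxit = 50))
  sc <- predict(mc, const)$scores
  expect_equal(max(sc) - min(sc), 0)
})

test_that("predict validates dimensions and handles empty input", {
  fm <- make_gauss_fm(8, 3, seed = 78, sep = 3)
  m <- train_lda(fm)
  expect_error(predict(m, matrix(0, 2, 2)), "feature count")
  out <- predict(m, fm$values[0, , drop = FALSE])
  expect_length(out$labels, 0)
  expect_length(out$scores, 0)
})

test_that("LOOCV yields one held-out prediction per unit and supports patient grouping", {
  fm <- make_gauss_fm(8, 2, seed = 79, sep = 5)
  fm$patient_ids <- rep(paste0("P", 1:4), each = 4)
  cv <- loocv_evaluate(fm, spec = list(kind = "lda"))
  expect_length(cv$predicted, 16)
  expect_equal(mean(cv$predicted == cv$truth), 1.0)
  cvp <- loocv_evaluate(fm, spec = list(kind = "lda"), grouping = "patient")
  expect_length(cvp$predicted, 16)
  expect_equal(mean(cvp$predicted == cvp$truth), 1.0)
})

test_that("held-out samples never influence fold-internal normalization", {
  fm <- make_gauss_fm(6, 2, seed = 80, sep = 4)
  # corrupt one held-out row with an extreme outlier; the fit for the folds
  # that exclude it must be unchanged
  fm_out <- fm
  fm_out$values[1, ] <- c(1e6, -1e6)
  train_rows <- 2:12
  p1 <- fit_min_max(subset_features(fm, rows = train_rows))
  p2 <- fit_min_max(subset_features(fm_out, rows = train_rows))
  expect_identical(p1, p2)
  # the model of the fold that excludes the outlier is bit-identical too
  m1 <- train_lda(apply_min_max(subset_features(fm, rows = train_rows), p1))
  m2 <- train_lda(apply_min_max(subset_features(fm_out, rows = train_rows), p2))
  expect_identical(m1$w, m2$w)
  expect_identical(m1$threshold, m2$threshold)
})
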