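# Feature-matrix assembly, min-max normalization, group t-test, split.

fake_groups <- function(n) {
  set.seed(51)
  g <- list()
  for (tag in c("W6", "M6", "A6", "non-filter"))
    g[[tag]] <- matrix(rnorm(n * 6), n, 6,
                       dimnames = list(NULL, c("e", "u", "m", "sd", "k", "s")))
  g
}

test_that("group subsets concatenate with the right widths and suffixes", {
  g <- fake_groups(10)
  y <- rep(c(1L, -1L), 5)
  expect_equal(ncol(build_feature_matrix(g, "non-filter", y)$values), 6)
  fm3 <- build_feature_matrix(g, c("A6", "M6", "W6"), y)
  expect_equal(ncol(fm3$values), 18)
  expect_equal(fm3$feature_names[1:6], c("e3", "u3", "m3", "sd3", "k3", "s3"))
  fm4 <- build_feature_matrix(g, c("A6", "M6", "W6", "non-filter"), y)
  expect_equal(ncol(fm4$values), 24)
  expect_true(all(c("e1", "k2", "sd3", "s4") %in% fm4$feature_names))
  expect_error(build_feature_matrix(g["W6"], c("W6", "M6"), y),
               "not computed")
})

test_that("min-max normalization follows Y = (X - min)/(max - min) with clipping", {
  fm <- feature_matrix(cbind(a = c(2, 4, 6), b = c(5, 5, 5)),
                       c(1L, -1L, 1L))
  pars <- fit_min_max(fm)
  expect_equal(unname(pars$min["a"]), 2)
  expect_equal(unname(pars$max["a"]), 6)
  expect_true(pars$degenerate["b"])
  norm <- apply_min_max(fm, pars)
  expect_equal(unname(norm$values[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(norm$values[, "b"]), c(0, 0, 0))
  outside <- feature_matrix(cbind(a = c(0, 10), b = c(1, 2)), c(1L, -1L))
  clipped <- apply_min_max(outside, pars)
  expect_equal(unname(clipped$values[, "a"]), c(0, 1))
  expect_equal(attr(clipped, "n_clipped"), 2)
})

test_that("normalization maps fitted columns onto [0,1] and preserves order", {
  set.seed(52)
  fm <- feature_matrix(matrix(rnorm(40 * 5, 100, 30), 40, 5),
                       rep(c(1L, -1L), 20))
  norm <- apply_min_max(fm, fit_min_max(fm))
  expect_equal(unname(apply(norm$values, 2, min)), rep(0, 5))
  expect_equal(unname(apply(norm$values, 2, max)), rep(1, 5))
  for (j in 1:5)
    expect_equal(order(norm$values[, j]), order(fm$values[, j]))
})

test_that("the pooled t-test matches the textbook formula and its limits", {
  set.seed(53)
  x1 <- rnorm(15, 1); x0 <- rnorm(12, 0)
  fm <- feature_matrix(cbind(f = c(x1, x0)),
                       c(rep(1L, 15), rep(-1L, 12)))
  res <- compare_groups_ttest(fm, "f")
  sp2 <- ((15 - 1) * var(x1) + (12 - 1) * var(x0)) / (15 + 12 - 2)
  t_ref <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / 15 + 1 / 12))
  expect_equal(res$t, t_ref, tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-abs(t_ref), 25), tolerance = 1e-9)
  expect_equal(res$f, t_ref^2, tolerance = 1e-9)
  # identical groups: no separation
  same <- feature_matrix(cbind(f = rep(c(1, 2), 6)),
                         rep(c(1L, -1L), each = 6))
  same$values[, 1] <- rep(c(1, 2), 6)
  same2 <- feature_matrix(cbind(f = c(1, 2, 1, 2, 1, 2, 1, 2)),
                          c(1L, 1L, 1L, 1L, -1L, -1L, -1L, -1L))
  r0 <- compare_groups_ttest(same2, "f")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # zero within-class variance, different means: p below 1e-10
  sep <- feature_matrix(cbind(f = c(rep(1, 6), rep(0, 6))),
                        c(rep(1L, 6), rep(-1L, 6)))
  expect_lt(compare_groups_ttest(sep, "f")$p, 1e-10)
})

test_that("the selection/validation split is stratified, disjoint and seeded", {
  fm <- make_gauss_fm(50, 3, seed = 54)
  sp <- split_selection_validation(fm, 0.5, seed = 99)
  expect_equal(nrow(sp$selection$values), 50)
  expect_equal(sum(sp$selection$labels == 1L), 25)
  expect_equal(sum(sp$validation$labels == -1L), 25)
  expect_length(intersect(sp$selection$sample_ids, sp$validation$sample_ids), 0)
  expect_setequal(c(sp$selection$sample_ids, sp$validation$sample_ids),
                  fm$sample_ids)
  sp2 <- split_selection_validation(fm, 0.5, seed = 99)
  expect_identical(sp$selection$sample_ids, sp2$selection$sample_ids)
  # different seeds almost surely differ
  others <- vapply(1:10, function(s)
    paste(split_selection_validation(fm, 0.5, seed = s)$selection$sample_ids,
          collapse = ","), "")
  expect_gt(length(unique(others)), 8)
})
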