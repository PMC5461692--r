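# Confusion metrics, ROC/AUC and report rendering.

test_that("confusion counts tally exactly", {
  truth <- c(rep(1L, 5), rep(-1L, 5))
  cm <- confusion_counts(truth, truth)
  expect_equal(unlist(cm[c("n_tp", "n_tn", "n_fp", "n_fn")]),
               c(n_tp = 5L, n_tn = 5L, n_fp = 0L, n_fn = 0L))
  allneg <- confusion_counts(c(1L, 1L, 1L, -1L, -1L), rep(-1L, 5))
  expect_equal(allneg$n_fn, 3L)
  expect_equal(allneg$n_tn, 2L)
  expect_equal(allneg$n_tp + allneg$n_fp, 0L)
  set.seed(91)
  t2 <- sample(c(1L, -1L), 60, TRUE); p2 <- sample(c(1L, -1L), 60, TRUE)
  cm2 <- confusion_counts(t2, p2)
  tal <- table(factor(t2, c(-1, 1)), factor(p2, c(-1, 1)))
  expect_equal(cm2$n_tp, unname(tal["1", "1"]))
  expect_equal(cm2$n_tn, unname(tal["-1", "-1"]))
  expect_error(confusion_counts(1L, c(1L, -1L)), "lengths")
  expect_error(confusion_counts(c(1L, 0L), c(1L, 1L)), "labels")
})

test_that("metrics follow the printed formulas with the zero-denominator rule", {
  perfect <- compute_metrics(confusion_matrix(7, 7, 0, 0))
  expect_equal(unlist(perfect[c("sen", "spc", "ppv", "npv", "acc")]),
               c(sen = 1, spc = 1, ppv = 1, npv = 1, acc = 1))
  allneg <- compute_metrics(confusion_matrix(0, 9, 0, 4))
  expect_equal(allneg$sen, 0)
  expect_equal(allneg$ppv, 0)
  expect_equal(allneg$spc, 1)
  expect_setequal(allneg$zero_denominator_flags, "ppv")
  nopos <- compute_metrics(confusion_matrix(0, 5, 0, 0))
  expect_setequal(nopos$zero_denominator_flags, c("sen", "ppv"))
})

test_that("accuracy is the prevalence-weighted mean of sensitivity and specificity", {
  set.seed(92)
  for (i in 1:20) {
    counts <- rmultinom(1, 50, rep(0.25, 4))
    if (counts[1] + counts[4] == 0 || counts[2] + counts[3] == 0) next
    cm <- confusion_matrix(counts[1], counts[2], counts[3], counts[4])
    r <- compute_metrics(cm)
    P <- cm$n_tp + cm$n_fn; N <- cm$n_tn + cm$n_fp
    expect_equal(r$acc, (r$sen * P + r$spc * N) / (P + N), tolerance = 1e-12)
    if (P > 0 && N > 0) {
      expect_gte(r$acc, min(r$sen, r$spc) - 1e-12)
      expect_lte(r$acc, max(r$sen, r$spc) + 1e-12)
    }
  }
})

test_that("swapping the positive class swaps SEN<->SPC and PPV<->NPV", {
  set.seed(93)
  truth <- sample(c(1L, -1L), 40, TRUE)
  pred <- sample(c(1L, -1L), 40, TRUE)
  a <- compute_metrics(confusion_counts(truth, pred))
  b <- compute_metrics(confusion_counts(-truth, -pred))
  expect_equal(a$sen, b$spc)
  expect_equal(a$ppv, b$npv)
  expect_equal(a$acc, b$acc)
})

test_that("ROC sweep covers the perfect, tied and random cases", {
  perfect <- roc_auc(c(3, 2, 1, -1, -2), c(1L, 1L, 1L, -1L, -1L))
  expect_equal(perfect$auc, 1.0)
  tied <- roc_auc(rep(0.5, 10), rep(c(1L, -1L), 5))
  expect_equal(tied$auc, 0.5)
  set.seed(94)
  scores <- round(rnorm(50), 1)  # rounding forces ties
  truth <- sample(c(1L, -1L), 50, TRUE)
  got <- roc_auc(scores, truth)
  expect_equal(got$auc, ref_auc_pairs(scores, truth), tolerance = 1e-12)
  expect_error(roc_auc(scores[truth == 1], truth[truth == 1]), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms and matches pROC", {
  set.seed(95)
  scores <- rnorm(60)
  truth <- sample(c(1L, -1L), 60, TRUE)
  base <- roc_auc(scores, truth)$auc
  expect_equal(roc_auc(exp(scores), truth)$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(2 * scores + 7, truth)$auc, base, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  p <- suppressMessages(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                            direction = "<", levels = c(-1, 1))))
  expect_equal(base, as.numeric(p), tolerance = 1e-12)
})

test_that("report rendering writes one row per configuration", {
  r <- compute_metrics(confusion_matrix(10, 12, 2, 1), auc = 0.9)
  d <- tempfile()
  paths <- render_reports(list("A6, M6, W6" = list(report = r,
                                                   selected = c("e1", "s1"))),
                          d)
  tab <- read.csv(file.path(d, "results.csv"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$name, "A6, M6, W6")
  expect_equal(tab$selected_features, "e1, s1")
  expect_equal(tab$ACC, 0.88)
  expect_error(render_reports(list(), d), "nothing to report")
})
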