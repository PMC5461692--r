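# First-order features: printed-formula cases, histogram behaviour,
# moment/affine invariances, oracle agreement.

test_that("histogram probabilities cover the documented cases", {
  h <- histogram_probabilities(rep(100, 9), n_bins = 8)
  expect_equal(h$p, c(1, rep(0, 7)))
  h2 <- histogram_probabilities(c(0, 0, 1, 1), n_bins = 2)
  expect_equal(h2$p, c(0.5, 0.5))
  expect_equal(sum(h2$p), 1)
  expect_error(histogram_probabilities(1:4, n_bins = 1), "n_bins")
})

test_that("uniform draws fill bins to within the binomial 5-sigma band", {
  set.seed(41)
  v <- runif(1000)
  h <- histogram_probabilities(v, n_bins = 10)
  sigma <- sqrt(0.1 * 0.9 / 1000)
  expect_true(all(abs(h$p - 0.1) < 5 * sigma))
})

test_that("constant and tiny ROIs produce the closed-form feature values", {
  fo <- extract_first_order(rep(100, 9))
  expect_equal(unname(fo[c("e", "u", "m", "sd", "k", "s")]),
               c(0, 1, 100, 0, 0, 0))
  expect_true(attr(fo, "degenerate"))
  fo3 <- extract_first_order(c(1, 2, 3), histogram_probabilities(c(1, 2, 3), 4))
  expect_equal(unname(fo3["m"]), 2)
  expect_equal(unname(fo3["sd"]), 1)
  expect_equal(unname(fo3["s"]), 0)
  expect_true(is.na(fo3["k"]))  # kurtosis needs n >= 4
  # two equal-mass bins: one bit of entropy, uniformity one half
  fo2 <- extract_first_order(c(0, 0, 1, 1), histogram_probabilities(c(0, 0, 1, 1), 2))
  expect_equal(unname(fo2["e"]), 1)
  expect_equal(unname(fo2["u"]), 0.5)
})

test_that("the excess-kurtosis formula reproduces its exact rational value", {
  fo <- extract_first_order(c(1, 2, 3, 4))
  expect_equal(unname(fo["k"]), -1.2, tolerance = 1e-12)
})

test_that("features match the naive oracle to 1e-9 on random ROIs", {
  for (i in 1:25) {
    v <- random_roi(n = sample(10:200, 1), seed = 400 + i)
    k <- sample(c(16, 64, 256), 1)
    h <- histogram_probabilities(v, n_bins = k)
    expect_equal(h$p, ref_histogram(v, k), tolerance = 1e-12)
    got <- extract_first_order(v, h)
    expect_equal(unname(got[c("e", "u", "m", "sd", "k", "s")]),
                 unname(ref_first_order(v, h$p)), tolerance = 1e-9)
  }
})

test_that("entropy and uniformity hit their analytic extremes", {
  # single occupied bin: e = 0, u = 1; near-uniform histogram approaches
  # e = log2(k), u = 1/k, and bounds hold on random histograms
  set.seed(42)
  k <- 16
  v_uni <- rep(seq_len(k), each = 50)  # one distinct level per bin
  h <- histogram_probabilities(v_uni, n_bins = k)
  fo <- extract_first_order(v_uni, h)
  expect_equal(unname(fo["e"]), log2(k), tolerance = 1e-9)
  expect_equal(unname(fo["u"]), 1 / k, tolerance = 1e-9)
  for (i in 1:20) {
    v <- random_roi(50, seed = 4200 + i)
    h <- histogram_probabilities(v, n_bins = k)
    fo <- extract_first_order(v, h)
    expect_gte(unname(fo["e"]), 0)
    expect_lte(unname(fo["e"]), log2(k) + 1e-12)
    expect_gte(unname(fo["u"]), 1 / k - 1e-12)
    expect_lte(unname(fo["u"]), 1)
    # e = 0 iff u = 1 iff single occupied bin
    expect_equal(fo[["e"]] == 0, sum(h$p > 0) == 1)
    expect_equal(fo[["u"]] == 1, sum(h$p > 0) == 1)
  }
})

test_that("moment features are order-invariant and affine-equivariant", {
  v <- random_roi(80, seed = 43)
  h <- function(x) histogram_probabilities(x, 64)
  base <- extract_first_order(v, h(v))
  perm <- extract_first_order(sample(v), h(v))
  expect_equal(base[c("m", "sd", "k", "s")], perm[c("m", "sd", "k", "s")])
  shifted <- extract_first_order(v + 50, h(v + 50))
  expect_equal(unname(shifted["m"]), unname(base["m"]) + 50)
  expect_equal(shifted[c("sd", "k", "s")], base[c("sd", "k", "s")],
               tolerance = 1e-9)
  scaled <- extract_first_order(v * 2.5 + 7, h(v * 2.5 + 7))
  expect_equal(scaled[c("k", "s")], base[c("k", "s")], tolerance = 1e-9)
})
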