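# First-order texture features of a masked ROI.
#
# Entropy and uniformity are functions of the gray-level histogram
# probabilities p(l); mean, standard deviation, skewness and kurtosis are
# sample moments of the raw HU values. Kurtosis is the bias-corrected
# EXCESS kurtosis (the Gaussian reference subtracted), skewness the
# bias-corrected third moment; both use the (n-1)-denominator sd.

FIRST_ORDER_NAMES <- c("e", "u", "m", "sd", "k", "s")
FIXED_HU_RANGE <- c(-1024, 3071)

#' Gray-level histogram probabilities of an ROI
#'
#' Equal-width bins over either the ROI's own min-max range or a fixed HU
#' range; the rightmost bin is closed. A degenerate range (all pixels equal)
#' yields a single occupied bin with probability 1.
#'
#' @param roi a `roi_sample` (or bare numeric vector of HU values).
#' @param n_bins number of bins `k` (>= 2), default 256.
#' @param range_policy `"roi_minmax"` (default) or `"fixed_hu"`.
#' @param fixed_range the HU range used under `"fixed_hu"`.
#' @return an object of class `hist_model`: `k`, `edges` (k+1 ascending),
#'   `p` (probabilities summing to 1).
#' @export
histogram_probabilities <- function(roi, n_bins = 256L,
                                    range_policy = c("roi_minmax", "fixed_hu"),
                                    fixed_range = FIXED_HU_RANGE) {
  range_policy <- match.arg(range_policy)
  v <- if (inherits(roi, "roi_sample")) roi$values else as.numeric(roi)
  if (length(v) < 1L) stopf("empty ROI")
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  rng <- if (range_policy == "roi_minmax") range(v) else fixed_range
  lo <- rng[1]; hi <- rng[2]
  if (hi <= lo) {
    p <- c(1, rep(0, n_bins - 1L))
    edges <- lo + seq(0, n_bins) # placeholder unit-width edges
  } else {
    idx <- floor((v - lo) / (hi - lo) * n_bins) + 1L
    idx[idx > n_bins] <- n_bins  # rightmost bin closed
    idx[idx < 1L] <- 1L          # clamp values below a fixed range
    p <- tabulate(idx, nbins = n_bins) / length(v)
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  structure(list(k = as.integer(n_bins), edges = edges, p = p),
            class = "hist_model")
}

#' First-order texture feature vector of an ROI
#'
#' Computes, over the masked HU values `a` with mean `a_bar` and the
#' histogram probabilities `p(l)`:
#' \describe{
#'   \item{e}{entropy, `-sum(p * log2(p))` with `0*log 0 = 0` (bits);
#'     randomness/irregularity of the intensity distribution}
#'   \item{u}{uniformity (energy), `sum(p^2)`, 1 for a single-level region}
#'   \item{m}{mean intensity (HU)}
#'   \item{sd}{sample standard deviation, `(n-1)` denominator (HU)}
#'   \item{k}{bias-corrected excess kurtosis:
#'     `n(n+1)/((n-1)(n-2)(n-3)) * sum(((a - a_bar)/sd)^4) -
#'      3 (n-1)^2/((n-2)(n-3))`}
#'   \item{s}{bias-corrected skewness:
#'     `n/((n-1)(n-2)) * sum(((a - a_bar)/sd)^3)`}
#' }
#' Features whose minimum sample size is not met (`n >= 2` for sd, 3 for
#' skewness, 4 for kurtosis) are reported as `NA`. If `sd == 0` the shape
#' statistics are defined as 0 and the `degenerate` attribute is set, so
#' constant regions survive the pipeline with finite values.
#'
#' @param roi a `roi_sample` (or numeric vector).
#' @param hist a `hist_model`; computed with defaults when omitted.
#' @return named numeric vector `c(e, u, m, sd, k, s)` with attributes
#'   `degenerate` (logical) and `group_tag`.
#' @export
extract_first_order <- function(roi, hist = NULL) {
  v <- if (inherits(roi, "roi_sample")) roi$values else as.numeric(roi)
  tag <- if (inherits(roi, "roi_sample")) roi$group_tag else "non-filter"
  n <- length(v)
  if (n < 1L) stopf("empty ROI")
  if (is.null(hist)) hist <- histogram_probabilities(v)
  p <- hist$p[hist$p > 0]
  e <- -sum(p * log2(p))
  u <- sum(hist$p^2)
  m <- mean(v)
  degenerate <- FALSE
  if (n >= 2L) {
    sdev <- stats::sd(v)
    if (sdev == 0) {
      degenerate <- TRUE
      s <- if (n >= 3L) 0 else NA_real_
      kf <- if (n >= 4L) 0 else NA_real_
    } else {
      z <- (v - m) / sdev
      s <- if (n >= 3L) n / ((n - 1) * (n - 2)) * sum(z^3) else NA_real_
      kf <- if (n >= 4L)
        n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
          3 * (n - 1)^2 / ((n - 2) * (n - 3))
      else NA_real_
    }
  } else {
    sdev <- NA_real_; s <- NA_real_; kf <- NA_real_
  }
  structure(c(e = e, u = u, m = m, sd = sdev, k = kf, s = s),
            degenerate = degenerate, group_tag = tag)
}
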