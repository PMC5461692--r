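# Gray-level co-occurrence matrix (GLCM) texture baseline.
#
# Masked pixels are quantized to `levels` gray levels over the ROI min-max;
# co-occurrences are accumulated over the requested offsets (both pixels of
# a pair must lie inside the mask), symmetrized and normalized to sum 1.
# Thirteen Haralick-style statistics are computed; "contrast" and "inertia"
# share one formula and are reported under both names (aliases).

GLCM_OFFSETS_D1 <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

GLCM_FEATURE_NAMES <- c(
  "angular_second_moment", "correlation", "entropy", "contrast",
  "inverse_difference_moment", "sum_average", "sum_entropy", "sum_variance",
  "variance", "difference_average", "inertia", "difference_variance",
  "difference_entropy")

glcm_quantize <- function(pixels, mask, levels) {
  v <- pixels[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(pixels), ncol(pixels))
  if (hi <= lo) {
    q[mask] <- 1L
  } else {
    idx <- floor((pixels[mask] - lo) / (hi - lo) * levels) + 1L
    idx[idx > levels] <- levels
    q[mask] <- as.integer(idx)
  }
  q
}

#' Normalized symmetric co-occurrence matrix of a masked region
#'
#' @param pixels numeric matrix (e.g. `ct_image$pixels`).
#' @param mask logical/numeric matrix or `roi_mask`; nonzero = inside.
#' @param levels number of gray levels (>= 2), default 64.
#' @param offsets list of `(dr, dc)` integer offsets; default distance 1 at
#'   0, 45, 90 and 135 degrees.
#' @return `levels` x `levels` matrix summing to 1.
#' @export
glcm_matrix <- function(pixels, mask, levels = 64L,
                        offsets = GLCM_OFFSETS_D1) {
  if (inherits(mask, "roi_mask")) mask <- mask$inside
  mask <- mask != 0
  stopifnot(identical(dim(mask), dim(pixels)))
  if (levels < 2L) stopf("levels must be >= 2")
  q <- glcm_quantize(pixels, mask, levels)
  nr <- nrow(q); nc <- ncol(q)
  counts <- matrix(0, levels, levels)
  npairs <- 0L
  pos <- which(mask, arr.ind = TRUE)
  for (off in offsets) {
    r2 <- pos[, 1L] + off[1L]
    c2 <- pos[, 2L] + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    a <- q[pos[ok, , drop = FALSE]]
    b <- q[cbind(r2[ok], c2[ok])]
    keep <- !is.na(b)
    if (!any(keep)) next
    a <- a[keep]; b <- b[keep]
    npairs <- npairs + length(a)
    counts <- counts +
      matrix(tabulate((a - 1L) * levels + b, nbins = levels * levels),
             levels, levels, byrow = TRUE)
  }
  if (npairs == 0L)
    stopf("no valid co-occurring pixel pair inside the mask for any offset")
  sym <- counts + t(counts)
  sym / sum(sym)
}

#' Thirteen GLCM texture features of a masked region
#'
#' Haralick-definition statistics of the normalized symmetric GLCM:
#' angular second moment, correlation, entropy (bits), contrast, inverse
#' difference moment, sum average, sum entropy, sum variance (dispersion of
#' the level-sum distribution about the sum average), variance, difference
#' average, inertia (= contrast), difference variance and difference
#' entropy. Correlation is defined as 0 when either marginal is constant.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of length 13.
#' @export
glcm_features <- function(pixels, mask, levels = 64L,
                          offsets = GLCM_OFFSETS_D1) {
  P <- glcm_matrix(pixels, mask, levels, offsets)
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)         # row level index
  j <- t(i)                             # column level index
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  ent2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

  # level-sum (2..2L) and absolute-difference (0..L-1) distributions
  sums <- as.vector(i + j); difs <- as.vector(abs(i - j)); pv <- as.vector(P)
  p_sum <- vapply(2:(2 * L), function(k) sum(pv[sums == k]), numeric(1))
  p_dif <- vapply(0:(L - 1), function(k) sum(pv[difs == k]), numeric(1))
  ks <- 2:(2 * L); kd <- 0:(L - 1)

  asm <- sum(P^2)
  corr <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  entropy <- ent2(pv)
  contrast <- sum((i - j)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum(ks * p_sum)
  sum_ent <- ent2(p_sum)
  sum_var <- sum((ks - sum_avg)^2 * p_sum)
  variance <- sum((i - mux)^2 * P)
  dif_avg <- sum(kd * p_dif)
  dif_var <- sum((kd - dif_avg)^2 * p_dif)
  dif_ent <- ent2(p_dif)

  stats::setNames(
    c(asm, corr, entropy, contrast, idm, sum_avg, sum_ent, sum_var,
      variance, dif_avg, contrast, dif_var, dif_ent),
    GLCM_FEATURE_NAMES)
}
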