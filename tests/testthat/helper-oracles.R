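# Independent brute-force oracles used across the suite. These are written
# as plain double loops / direct formula transcriptions, deliberately
# sharing no code path with the package implementations they check.

# --- first-order features -------------------------------------------------

ref_histogram <- function(v, k, lo = min(v), hi = max(v)) {
  if (hi <= lo) return(c(1, rep(0, k - 1)))
  counts <- numeric(k)
  width <- (hi - lo) / k
  for (x in v) {
    b <- 1L
    while (b < k && x >= lo + b * width) b <- b + 1L
    counts[b] <- counts[b] + 1
  }
  counts / length(v)
}

ref_first_order <- function(v, p) {
  n <- length(v)
  e <- 0
  for (pi in p) if (pi > 0) e <- e - pi * log2(pi)
  u <- sum(p^2)
  m <- sum(v) / n
  sdev <- sqrt(sum((v - m)^2) / (n - 1))
  z3 <- sum(((v - m) / sdev)^3)
  z4 <- sum(((v - m) / sdev)^4)
  s <- n / ((n - 1) * (n - 2)) * z3
  k4 <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * z4 -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  c(e = e, u = u, m = m, sd = sdev, k = k4, s = s)
}

# --- GLCM -----------------------------------------------------------------

ref_glcm_features <- function(pixels, mask, levels, offsets) {
  v <- pixels[mask]
  lo <- min(v); hi <- max(v)
  nr <- nrow(pixels); nc <- ncol(pixels)
  q <- matrix(NA_integer_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) if (mask[r, c]) {
    if (hi <= lo) q[r, c] <- 1L
    else {
      b <- floor((pixels[r, c] - lo) / (hi - lo) * levels) + 1
      q[r, c] <- as.integer(min(b, levels))
    }
  }
  C <- matrix(0, levels, levels)
  for (off in offsets) for (r in 1:nr) for (c in 1:nc) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (!is.na(q[r, c]) && r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        !is.na(q[r2, c2]))
      C[q[r, c], q[r2, c2]] <- C[q[r, c], q[r2, c2]] + 1
  }
  P <- C + t(C)
  P <- P / sum(P)
  L <- levels
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; for (i in 1:L) mux <- mux + i * px[i]
  muy <- 0; for (j in 1:L) muy <- muy + j * py[j]
  sx <- sqrt(sum((1:L - mux)^2 * px)); sy <- sqrt(sum((1:L - muy)^2 * py))
  asm <- 0; ent <- 0; con <- 0; idm <- 0; corr_num <- 0; varia <- 0
  psum <- numeric(2 * L); pdif <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    pij <- P[i, j]
    asm <- asm + pij^2
    if (pij > 0) ent <- ent - pij * log2(pij)
    con <- con + (i - j)^2 * pij
    idm <- idm + pij / (1 + (i - j)^2)
    corr_num <- corr_num + i * j * pij
    varia <- varia + (i - mux)^2 * pij
    psum[i + j] <- psum[i + j] + pij
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + pij
  }
  corr <- if (sx > 0 && sy > 0) (corr_num - mux * muy) / (sx * sy) else 0
  sa <- sum((1:(2 * L)) * psum)
  se <- 0; for (p in psum) if (p > 0) se <- se - p * log2(p)
  sv <- sum(((1:(2 * L)) - sa)^2 * psum)
  da <- sum((0:(L - 1)) * pdif)
  dv <- sum(((0:(L - 1)) - da)^2 * pdif)
  de <- 0; for (p in pdif) if (p > 0) de <- de - p * log2(p)
  c(angular_second_moment = asm, correlation = corr, entropy = ent,
    contrast = con, inverse_difference_moment = idm, sum_average = sa,
    sum_entropy = se, sum_variance = sv, variance = varia,
    difference_average = da, inertia = con, difference_variance = dv,
    difference_entropy = de)
}

# --- kNN / selection ------------------------------------------------------

ref_knn_loocv <- function(x, y, k) {
  n <- nrow(x)
  correct <- 0
  for (i in 1:n) {
    d <- rep(Inf, n)
    for (j in 1:n) if (j != i) d[j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    nb <- order(d)[1:k]
    vote <- sum(y[nb])
    pred <- if (vote > 0) 1 else -1
    if (pred == y[i]) correct <- correct + 1
  }
  correct / n
}

# plain sequential forward selection (no floating), best over all sizes
ref_sfs <- function(fm, k) {
  feats <- fm$feature_names
  current <- character(0)
  best_val <- -Inf; best_set <- NULL
  repeat {
    remaining <- setdiff(feats, current)
    if (length(remaining) == 0) break
    vals <- sapply(remaining, function(f)
      knn_loocv_accuracy(fm, c(current, f), k = k))
    current <- c(current, remaining[which.max(vals)])
    if (max(vals) > best_val) {
      best_val <- max(vals); best_set <- current
    }
  }
  list(best_criterion = best_val, selected = best_set)
}

# exhaustive search over all non-empty subsets
ref_exhaustive <- function(fm, k) {
  feats <- fm$feature_names
  best <- -Inf
  for (m in 1:(2^length(feats) - 1)) {
    sub <- feats[bitwAnd(m, 2^(seq_along(feats) - 1)) > 0]
    v <- knn_loocv_accuracy(fm, sub, k = k)
    if (v > best) best <- v
  }
  best
}

# --- AUC ------------------------------------------------------------------

ref_auc_pairs <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == -1]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# --- data builders --------------------------------------------------------

make_gauss_fm <- function(n_per_class, p, seed, sep = 2) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per_class * p, mean = sep / 2), n_per_class, p)
  x0 <- matrix(rnorm(n_per_class * p, mean = -sep / 2), n_per_class, p)
  feature_matrix(rbind(x1, x0), c(rep(1L, n_per_class), rep(-1L, n_per_class)))
}

random_roi <- function(n, seed) {
  set.seed(seed)
  round(runif(n, -200, 400), 1)
}
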