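# 3x3 denoising filter bank: moving average, median and adaptive Wiener.
#
# Filters run on the FULL image before masking, so that artificial values
# are never blended across the ROI boundary; borders use edge replication.
# Photon noise in CT is pixel-scale and weakly correlated, so a small
# spatial window suppresses it while regional tissue texture survives.

pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# n x w^2 matrix whose rows are the window neighbourhoods of each pixel
neighbourhoods <- function(m, window) {
  r <- (window - 1L) %/% 2L
  p <- pad_replicate(m, r)
  nr <- nrow(m); nc <- ncol(m)
  cols <- vector("list", window * window)
  k <- 0L
  for (dc in seq_len(window)) for (dr in seq_len(window)) {
    k <- k + 1L
    cols[[k]] <- as.vector(p[dr:(dr + nr - 1L), dc:(dc + nc - 1L)])
  }
  do.call(cbind, cols)
}

window_mean <- function(m, window) {
  nb <- neighbourhoods(m, window)
  matrix(rowMeans(nb), nrow(m), ncol(m))
}

check_window <- function(window) {
  if (!is_odd_window(window))
    stopf("filter window must be an odd integer >= 3 (got %s)",
          paste(window, collapse = ","))
}

filtered_image <- function(image, pixels, tag) {
  ct_image(pixels, pixel_spacing_mm = image$pixel_spacing_mm,
           source_id = image$source_id, group_tag = tag, hu_range = NULL)
}

#' Moving-average filter
#'
#' Each output pixel is the arithmetic mean of the `window` x `window`
#' neighbourhood centred on it, with edge replication at borders.
#'
#' @param image a `ct_image`.
#' @param window odd integer >= 3 (default 3).
#' @return a filtered `ct_image` tagged `"A"`.
#' @export
average_filter <- function(image, window = 3L) {
  check_window(window)
  filtered_image(image, window_mean(image$pixels, window), "A")
}

#' Median filter
#'
#' Each output pixel is the median of its neighbourhood; robust to impulse
#' noise such as isolated photon-starved pixels.
#'
#' @inheritParams average_filter
#' @return a filtered `ct_image` tagged `"M"`.
#' @export
median_filter <- function(image, window = 3L) {
  check_window(window)
  nb <- neighbourhoods(image$pixels, window)
  # odd count: median is the middle order statistic
  mid <- (ncol(nb) + 1L) %/% 2L
  med <- apply(nb, 1L, function(v) sort.int(v, partial = mid)[mid])
  filtered_image(image, matrix(med, image$n_rows, image$n_cols), "M")
}

#' Adaptive Wiener filter
#'
#' Local-statistics (Lee-type) Wiener filter: with local mean `mu` and local
#' variance `s2` over the window and noise power `nu` estimated as the mean
#' of all local variances, each pixel maps to
#' `mu + max(s2 - nu, 0) / max(s2, nu) * (pixel - mu)`.
#' Flat regions collapse to their local mean; high-variance structure is
#' preserved.
#'
#' @inheritParams average_filter
#' @return a filtered `ct_image` tagged `"W"`.
#' @export
wiener_filter <- function(image, window = 3L) {
  check_window(window)
  m <- image$pixels
  mu <- window_mean(m, window)
  s2 <- window_mean(m * m, window) - mu * mu
  s2[s2 < 0] <- 0  # guard FP negatives
  nu <- mean(s2)
  den <- pmax(s2, nu)
  gain <- ifelse(den > 0, pmax(s2 - nu, 0) / den, 0)
  filtered_image(image, mu + gain * (m - mu), "W")
}

#' Filter specification
#'
#' @param kind one of `"none"`, `"average"`, `"median"`, `"wiener"`.
#' @param window odd integer >= 3; ignored for `"none"`.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(kind = c("none", "average", "median", "wiener"),
                        window = 3L) {
  kind <- match.arg(kind)
  if (kind != "none") check_window(window)
  structure(list(kind = kind, window = as.integer(window)),
            class = "filter_spec")
}

#' Apply a list of filter specs to one image
#'
#' @param image a `ct_image`.
#' @param specs non-empty list of `filter_spec` objects (or kind strings).
#' @return list of `ct_image`s, one per spec, order preserved, tagged
#'   `"non-filter"`, `"A"`, `"M"` or `"W"`.
#' @export
build_filter_bank <- function(image, specs) {
  if (length(specs) == 0L) stopf("filter bank needs at least one spec")
  lapply(specs, function(sp) {
    if (is.character(sp)) sp <- filter_spec(sp)
    switch(sp$kind,
           none = filtered_image(image, image$pixels, "non-filter"),
           average = average_filter(image, sp$window),
           median = median_filter(image, sp$window),
           wiener = wiener_filter(image, sp$window))
  })
}
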