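#' thyrotex: first-order texture analysis of thyroid CT regions of interest
#'
#' Masked-ROI texture feature extraction under a 3x3 denoising filter bank,
#' min-max normalization, SFFS feature selection, SVM/LDA/ANN
#' classification, confusion-matrix/ROC evaluation and a synthetic CT
#' phantom generator.
#'
#' @keywords internal
#' @aliases thyrotex-package
"_PACKAGE"

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seeds below 2^31, derived from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_odd_window <- function(window) {
  length(window) == 1L && is.finite(window) && window >= 3 && window %% 2 == 1
}
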