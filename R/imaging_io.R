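# Masked-ROI ingestion: CT slices in HU, binary masks, masked pixel samples.
#
# The ROI is defined by the SET of pixels under the nonzero mask cells.
# Outside pixels are excluded from every downstream statistic — they are
# never carried along as zeros, which would corrupt histogram and moment
# features of the region.

HU_SANITY_RANGE <- c(-1100, 3200)
MIN_ROI_PIXELS <- 16L

#' Construct a CT image object
#'
#' @param pixels numeric matrix of Hounsfield-unit values.
#' @param pixel_spacing_mm optional length-2 positive numeric.
#' @param source_id text identifier.
#' @param group_tag filter provenance tag (`"non-filter"` for raw images).
#' @param hu_range sanity bounds for HU values.
#' @return an object of class `ct_image`.
#' @export
ct_image <- function(pixels, pixel_spacing_mm = NULL, source_id = "",
                     group_tag = "non-filter", hu_range = HU_SANITY_RANGE) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels))) stopf("CT image contains non-finite pixels")
  if (!is.null(hu_range) &&
      (min(pixels) < hu_range[1] || max(pixels) > hu_range[2]))
    stopf("HU values outside sanity range [%g, %g]", hu_range[1], hu_range[2])
  if (!is.null(pixel_spacing_mm))
    stopifnot(length(pixel_spacing_mm) == 2, all(pixel_spacing_mm > 0))
  structure(
    list(pixels = pixels, n_rows = nrow(pixels), n_cols = ncol(pixels),
         pixel_spacing_mm = pixel_spacing_mm, source_id = source_id,
         group_tag = group_tag),
    class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %dx%d px, HU [%g, %g], source '%s', group '%s'\n",
              x$n_rows, x$n_cols, min(x$pixels), max(x$pixels),
              x$source_id, x$group_tag))
  invisible(x)
}

#' Construct a binary ROI mask
#'
#' Any nonzero cell is inside the region.
#'
#' @param inside matrix (logical or numeric); nonzero means inside.
#' @param image optional `ct_image` the mask must match in shape.
#' @param min_pixels minimum region size (default 16).
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(inside, image = NULL, min_pixels = MIN_ROI_PIXELS) {
  stopifnot(is.matrix(inside))
  inside <- inside != 0
  if (!is.null(image) &&
      !identical(dim(inside), c(image$n_rows, image$n_cols)))
    stopf("mask shape %dx%d does not match image shape %dx%d",
          nrow(inside), ncol(inside), image$n_rows, image$n_cols)
  n_inside <- sum(inside)
  if (n_inside == 0L) stopf("empty ROI: mask has no nonzero cells")
  if (n_inside < min_pixels)
    stopf("ROI too small: %d pixels (minimum %d)", n_inside, min_pixels)
  structure(list(inside = inside, n_inside = as.integer(n_inside)),
            class = "roi_mask")
}

#' Gather the masked pixel sample of a region
#'
#' Implements the ROI-extraction step in which the image is combined with
#' its binary mask: the result is the multiset of HU values at nonzero mask
#' cells, in row-major order. Pixels outside the mask are excluded, not
#' zeroed.
#'
#' @param image a `ct_image`.
#' @param mask a `roi_mask` of matching shape.
#' @param label class label: `"nodule"`, `"normal"` or `"unknown"`.
#' @return an object of class `roi_sample` with fields `values`, `n`,
#'   `label`, `group_tag`, `source_id`.
#' @export
apply_mask <- function(image, mask, label = c("unknown", "nodule", "normal")) {
  label <- match.arg(label)
  stopifnot(inherits(image, "ct_image"), inherits(mask, "roi_mask"))
  if (!identical(dim(mask$inside), c(image$n_rows, image$n_cols)))
    stopf("mask shape does not match image shape")
  # row-major gather: walk rows of the transposed (column-major) matrices
  tp <- t(image$pixels)
  tm <- t(mask$inside)
  values <- tp[tm]
  structure(
    list(values = as.numeric(values), n = mask$n_inside, label = label,
         group_tag = image$group_tag, source_id = image$source_id),
    class = "roi_sample")
}

#' Load a CT slice from file and convert stored values to HU
#'
#' DICOM stored values are mapped to Hounsfield units via
#' `HU = stored * RescaleSlope + RescaleIntercept`.
#'
#' @param path DICOM file path.
#' @param rescale_policy `"hu"` applies the rescale (default; missing tags
#'   fall back to slope 1, intercept 0 with a warning), `"strict"` errors on
#'   missing rescale tags, `"raw"` returns stored values unchanged.
#' @param hu_range sanity bounds, or `NULL` to skip the check.
#' @return a `ct_image`.
#' @export
load_ct_image <- function(path, rescale_policy = c("hu", "strict", "raw"),
                          hu_range = HU_SANITY_RANGE) {
  rescale_policy <- match.arg(rescale_policy)
  d <- read_dicom(path)
  if (!identical(d$modality, "CT"))
    warnf("modality '%s' is not CT: %s", d$modality, path)
  slope <- d$slope
  intercept <- d$intercept
  if (rescale_policy == "raw") {
    slope <- 1; intercept <- 0; hu_range <- NULL
  } else if (is.null(slope) || is.null(intercept)) {
    if (rescale_policy == "strict")
      stopf("missing RescaleSlope/RescaleIntercept tags: %s", path)
    warnf("missing rescale tags, using slope 1 / intercept 0: %s", path)
    slope <- 1; intercept <- 0
  }
  ct_image(d$stored * slope + intercept,
           pixel_spacing_mm = d$pixel_spacing_mm,
           source_id = if (nzchar(d$patient_id)) d$patient_id
                       else tools::file_path_sans_ext(basename(path)),
           hu_range = hu_range)
}

#' Load a binary ROI mask (DICOM, PNG or NIfTI)
#'
#' Format is inferred from the file extension; nonzero cells are inside.
#'
#' @param path mask file path.
#' @param image the paired `ct_image`; the mask must match its shape.
#' @param min_pixels minimum region size.
#' @return a `roi_mask`.
#' @export
load_mask <- function(path, image, min_pixels = MIN_ROI_PIXELS) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  grid <- switch(
    ext,
    png = {
      arr <- png::readPNG(path)
      if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
      arr
    },
    nii = {
      arr <- as.array(RNifti::readNifti(path))
      if (length(dim(arr)) > 2L) arr <- arr[, , 1L]
      arr
    },
    read_dicom(path)$stored  # DICOM default; stored values used directly
  )
  roi_mask(grid, image = image, min_pixels = min_pixels)
}

#' Read an ROI manifest CSV
#'
#' Expected columns: `image_path`, `mask_path`, `label`, `patient_id`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with absolute paths.
#' @export
read_roi_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path", "label", "patient_id")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stopf("manifest lacks columns: %s", paste(missing, collapse = ", "))
  if (!all(m$label %in% c("nodule", "normal", "unknown")))
    stopf("manifest labels must be nodule/normal/unknown")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$image_path <- fix(m$image_path)
  m$mask_path <- fix(m$mask_path)
  m
}
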