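# Seeded synthetic CT phantoms of thyroid regions.
#
# Normal thyroid tissue absorbs iodine and images homogeneously around
# 90-120 HU; nodule tissue does not (base mean below 70 HU) and is
# heterogeneous, optionally carrying water-like cystic blobs (~10 HU) and
# bright calcification specks (~300 HU, i.e. well above 120 HU). Tissue
# heterogeneity is modeled as a spatially smooth random field (regional
# structure such as necrosis or haemorrhage), while photon noise is
# additive pixel-iid Gaussian — the separation in spatial scale is what a
# 3x3 denoising filter exploits. The region sits in a muscle-like soft
# tissue background (configurable, e.g. -1000 for air).

#' Phantom generation parameters
#'
#' Defaults encode the study conditions: normal mean drawn from
#' `[90, 120]` HU with sd 8; nodule mean drawn from `[30, 70]` HU with sd
#' 25; cysts near water HU; calcifications at 300 HU; additive photon noise
#' sd 5 HU. `sd_jitter` is the lognormal sdlog applied to the class texture
#' sd per phantom, giving the within-class spread without which single
#' features would separate the classes trivially.
#'
#' @param class `"normal"` or `"nodule"`.
#' @param image_size `(rows, cols)`, default `c(64, 64)`.
#' @param roi_axes ellipse semi-axes `(rows, cols)` in px, or `NULL` to draw
#'   from `[7, 12] x [9, 14]`.
#' @param normal_mean_hu,nodule_mean_hu class mean HU, or `NULL` to draw
#'   from the ranges above.
#' @param normal_sd_hu,nodule_sd_hu texture field amplitude (HU).
#' @param sd_jitter lognormal sdlog multiplying the texture sd per phantom.
#' @param p_cyst,p_calc probabilities of inserting a cystic blob /
#'   calcification specks into a nodule.
#' @param cyst_hu,calc_hu lesion intensities (HU).
#' @param lesion_radius_px cyst radius range in px.
#' @param noise_sd_hu additive photon-noise sd (HU).
#' @param background_hu outside-mask intensity (default 50, muscle-like
#'   neck soft tissue; set -1000 for air).
#' @param texture_smooth half-width of the field-smoothing kernel (px).
#' @param seed integer seed; the phantom is fully determined by it.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(class = c("normal", "nodule"),
                           image_size = c(64L, 64L), roi_axes = NULL,
                           normal_mean_hu = NULL, normal_sd_hu = 8,
                           nodule_mean_hu = NULL, nodule_sd_hu = 25,
                           sd_jitter = 0.4,
                           p_cyst = 0.35, p_calc = 0.3,
                           cyst_hu = 10, calc_hu = 300,
                           lesion_radius_px = c(2, 4), noise_sd_hu = 5,
                           background_hu = 50, texture_smooth = 2L,
                           seed = 1L) {
  class <- match.arg(class)
  stopifnot(p_cyst >= 0, p_cyst <= 1, p_calc >= 0, p_calc <= 1,
            normal_sd_hu >= 0, nodule_sd_hu >= 0, noise_sd_hu >= 0,
            length(image_size) == 2, all(image_size >= 16))
  if (!is.null(roi_axes) &&
      any(2 * roi_axes + 2 > image_size))
    stopf("ROI ellipse does not fit inside the image")
  structure(as.list(environment()), class = "phantom_config")
}

smooth_unit_field <- function(nr, nc, half) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (half > 0) {
    w <- 2L * as.integer(half) + 1L
    z <- window_mean(z, w)
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z / s else z
}

disk_cells <- function(nr, nc, r0, c0, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= radius^2
}

#' Generate one phantom CT slice with its ROI mask
#'
#' Fully determined by `config$seed`: elliptical mask, class-specific base
#' intensity plus a smooth texture field, optional cyst/calcification
#' lesions for nodules, photon noise everywhere.
#'
#' @param config a [phantom_config()].
#' @return list: `image` (a `ct_image`), `mask` (a `roi_mask`), `label`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    nr <- config$image_size[1L]; nc <- config$image_size[2L]
    ax <- config$roi_axes %||%
      c(stats::runif(1, 7, 12), stats::runif(1, 9, 14))
    r0 <- nr / 2 + stats::runif(1, -3, 3)
    c0 <- nc / 2 + stats::runif(1, -3, 3)
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    inside <- ((rr - r0) / ax[1L])^2 + ((cc - c0) / ax[2L])^2 <= 1

    is_nodule <- config$class == "nodule"
    mean_hu <- if (is_nodule)
      config$nodule_mean_hu %||% stats::runif(1, 30, 70)
    else
      config$normal_mean_hu %||% stats::runif(1, 90, 120)
    sd_hu <- (if (is_nodule) config$nodule_sd_hu else config$normal_sd_hu) *
      exp(stats::rnorm(1, 0, config$sd_jitter))

    field <- smooth_unit_field(nr, nc, config$texture_smooth)
    img <- matrix(config$background_hu, nr, nc)
    tissue <- mean_hu + sd_hu * field
    img[inside] <- tissue[inside]

    if (is_nodule) {
      if (stats::runif(1) < config$p_cyst) {
        rad <- stats::runif(1, config$lesion_radius_px[1L],
                            config$lesion_radius_px[2L])
        if (2 * rad > 2 * min(ax)) stopf("lesion larger than ROI")
        th <- stats::runif(1, 0, 2 * pi); u <- sqrt(stats::runif(1)) * 0.6
        cyst <- disk_cells(nr, nc, r0 + u * ax[1L] * sin(th),
                           c0 + u * ax[2L] * cos(th), rad) & inside
        img[cyst] <- config$cyst_hu + stats::rnorm(sum(cyst), 0, 3)
      }
      if (stats::runif(1) < config$p_calc) {
        for (i in seq_len(sample(1:3, 1))) {
          th <- stats::runif(1, 0, 2 * pi); u <- sqrt(stats::runif(1)) * 0.7
          speck <- disk_cells(nr, nc, r0 + u * ax[1L] * sin(th),
                              c0 + u * ax[2L] * cos(th),
                              stats::runif(1, 1, 2)) & inside
          img[speck] <- config$calc_hu + stats::rnorm(sum(speck), 0, 20)
        }
      }
    }

    if (config$noise_sd_hu > 0)
      img <- img + stats::rnorm(nr * nc, 0, config$noise_sd_hu)
    img <- round(img)  # CT images carry integer HU stored values
    img[img < HU_SANITY_RANGE[1]] <- HU_SANITY_RANGE[1]
    img[img > HU_SANITY_RANGE[2]] <- HU_SANITY_RANGE[2]

    list(image = ct_image(img, pixel_spacing_mm = c(1, 1),
                          source_id = sprintf("phantom_%s_%d",
                                              config$class, config$seed)),
         mask = roi_mask(inside),
         label = config$class)
  })
}

#' Generate a seeded phantom dataset
#'
#' Per-sample seeds are derived deterministically from the master seed.
#' Phantoms are grouped into synthetic patients of 2-3 images each (as in a
#' clinical series where each case contributes several slices); images of
#' one patient share the drawn mean HU and texture amplitude. With
#' `dir = NULL` everything stays in memory; otherwise DICOM image/mask
#' pairs (slope 1, intercept -1024 — the dialect [load_ct_image()] reads)
#' and a manifest CSV are written.
#'
#' @param n_normal,n_nodule per-class sample counts (>= 1).
#' @param seed master integer seed.
#' @param dir output directory, or `NULL` for in-memory results.
#' @param config a template [phantom_config()]; its class/mean/seed fields
#'   are overridden per sample.
#' @return list: `samples` (list of `generate_phantom` outputs; `NULL` when
#'   written to disk), `manifest` (data.frame: image_path, mask_path,
#'   label, patient_id).
#' @export
generate_dataset <- function(n_normal, n_nodule, seed = 1L, dir = NULL,
                             config = phantom_config()) {
  stopifnot(n_normal >= 1L, n_nodule >= 1L)
  n <- n_normal + n_nodule
  seeds <- derive_seeds(seed, 3L * n)
  plan <- with_seed(seeds[1L], {
    rows <- list(); pid <- 0L
    for (cls in c("normal", "nodule")) {
      left <- if (cls == "normal") n_normal else n_nodule
      while (left > 0L) {
        m <- min(left, sample(2:3, 1L))
        pid <- pid + 1L
        mean_hu <- if (cls == "nodule") stats::runif(1, 30, 70)
                   else stats::runif(1, 90, 120)
        sd_mult <- exp(stats::rnorm(1, 0, config$sd_jitter))
        for (j in seq_len(m))
          rows[[length(rows) + 1L]] <- data.frame(
            label = cls, patient_id = sprintf("P%03d", pid),
            mean_hu = mean_hu, sd_mult = sd_mult, stringsAsFactors = FALSE)
        left <- left - m
      }
    }
    do.call(rbind, rows)
  })
  plan$sample_id <- sprintf("%s_%03d", plan$label, seq_len(n))
  plan$seed <- seeds[n + seq_len(n)]

  samples <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$class <- plan$label[i]
    cfg$seed <- plan$seed[i]
    cfg$sd_jitter <- 0  # patient-level amplitude already drawn
    if (plan$label[i] == "nodule") {
      cfg$nodule_mean_hu <- plan$mean_hu[i]
      cfg$nodule_sd_hu <- config$nodule_sd_hu * plan$sd_mult[i]
    } else {
      cfg$normal_mean_hu <- plan$mean_hu[i]
      cfg$normal_sd_hu <- config$normal_sd_hu * plan$sd_mult[i]
    }
    samples[[i]] <- generate_phantom(cfg)
  }

  if (is.null(dir)) {
    manifest <- data.frame(
      image_path = NA_character_, mask_path = NA_character_,
      label = plan$label, patient_id = plan$patient_id,
      sample_id = plan$sample_id, stringsAsFactors = FALSE)
    return(list(samples = samples, manifest = manifest))
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    image_path = file.path(dir, paste0(plan$sample_id, "_img.dcm")),
    mask_path = file.path(dir, paste0(plan$sample_id, "_mask.dcm")),
    label = plan$label, patient_id = plan$patient_id,
    sample_id = plan$sample_id, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    write_dicom(samples[[i]]$image$pixels, manifest$image_path[i],
                source_id = plan$patient_id[i])
    write_dicom(samples[[i]]$mask$inside * 1, manifest$mask_path[i],
                slope = 1, intercept = 0, modality = "OT",
                source_id = plan$patient_id[i])
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(samples = NULL, manifest = manifest)
}
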