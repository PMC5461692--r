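# Minimal single-frame DICOM codec (Explicit/Implicit VR Little Endian).
#
# Only the tags the CT pipeline needs are interpreted: Modality, Rows,
# Columns, PixelSpacing, BitsAllocated, PixelRepresentation, RescaleSlope,
# RescaleIntercept, PatientID and PixelData. Everything else is skipped by
# length. The writer emits Explicit VR Little Endian with a standard
# 128-byte preamble + "DICM" + group 0002 file meta, which is the dialect
# the reader (and pydicom) consumes.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.1417"

dcm_vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_pad <- function(x, pad = as.raw(0x20)) {
  if (length(x) %% 2 == 1) c(x, pad) else x
}

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_uint32 <- function(x) {
  # writeBin has no unsigned 32-bit; values here stay far below 2^31
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

dcm_element <- function(group, element, vr, value_raw) {
  value_raw <- dcm_pad(value_raw, if (vr == "UI") as.raw(0) else as.raw(0x20))
  head <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (vr %in% dcm_vr_long) {
    c(head, as.raw(c(0, 0)), dcm_uint32(length(value_raw)), value_raw)
  } else {
    c(head, dcm_uint16(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, element, vr, s) dcm_element(group, element, vr, charToRaw(s))
dcm_us  <- function(group, element, x) dcm_element(group, element, "US", dcm_uint16(x))

# Deterministic pseudo-UID from a text identifier.
dcm_uid_for <- function(source_id) {
  h <- sum(utf8ToInt(source_id) * seq_along(utf8ToInt(source_id))) %% 999999L
  paste0(UID_ROOT, ".", h + 1L, ".", nchar(source_id) + 1L)
}

#' Write a single-frame CT DICOM file
#'
#' Stores a Hounsfield-unit pixel grid as unsigned 16-bit values under the
#' linear rescale `stored = (HU - intercept) / slope`, so that a compliant
#' reader recovers HU via `stored * RescaleSlope + RescaleIntercept`.
#' Matrices are written in DICOM row-major pixel order.
#'
#' @param pixels numeric matrix of HU values.
#' @param path output file path.
#' @param slope,intercept rescale parameters (defaults 1 and -1024).
#' @param pixel_spacing_mm length-2 numeric, row/column spacing in mm.
#' @param modality DICOM modality code, default `"CT"`.
#' @param source_id identifier stored as PatientID and used to derive UIDs.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, slope = 1, intercept = -1024,
                        pixel_spacing_mm = c(1, 1), modality = "CT",
                        source_id = "thyrotex") {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  stored <- round((pixels - intercept) / slope)
  if (any(stored < 0 | stored > 65535))
    stopf("pixel values out of unsigned 16-bit range after rescale")
  # row-major order: transpose the column-major R matrix
  stored_vec <- as.integer(t(stored))
  px_raw <- writeBin(stored_vec, raw(), size = 2, endian = "little")

  sop_uid <- dcm_uid_for(paste0(source_id, basename(path)))
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", UID_CT_STORAGE),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    dcm_str(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint32(length(meta_body))),
            meta_body)

  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_CT_STORAGE),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", modality),
    dcm_str(0x0010, 0x0020, "LO", source_id),
    dcm_us(0x0028, 0x0002, 1),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, nrow(pixels)),
    dcm_us(0x0028, 0x0011, ncol(pixels)),
    dcm_str(0x0028, 0x0030, "DS",
            paste(format(pixel_spacing_mm, trim = TRUE), collapse = "\\")),
    dcm_us(0x0028, 0x0100, 16),
    dcm_us(0x0028, 0x0101, 16),
    dcm_us(0x0028, 0x0102, 15),
    dcm_us(0x0028, 0x0103, 0),
    dcm_str(0x0028, 0x1052, "DS", format(intercept, trim = TRUE)),
    dcm_str(0x0028, 0x1053, "DS", format(slope, trim = TRUE)),
    dcm_element(0x7FE0, 0x0010, "OW", px_raw)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

read_uint16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}
read_uint32 <- function(bytes, at) {
  sum(as.numeric(bytes[at:(at + 3L)]) * c(1, 256, 65536, 16777216))
}

# Parse a DICOM byte stream into a list keyed by "gggg,eeee" hex tags.
dcm_parse <- function(bytes) {
  n <- length(bytes)
  if (n < 140 || rawToChar(bytes[129:132]) != "DICM")
    stopf("not a DICOM file (missing DICM magic)")
  pos <- 133L
  explicit <- TRUE
  ts <- TS_EXPLICIT_LE
  out <- list()
  in_meta <- TRUE
  while (pos + 7L <= n) {
    group <- read_uint16(bytes, pos)
    element <- read_uint16(bytes, pos + 2L)
    if (in_meta && group != 0x0002) {
      in_meta <- FALSE
      explicit <- !identical(ts, TS_IMPLICIT_LE)
    }
    use_explicit <- in_meta || explicit
    if (use_explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% dcm_vr_long) {
        len <- read_uint32(bytes, pos + 8L)
        val_at <- pos + 12L
      } else {
        len <- read_uint16(bytes, pos + 6L)
        val_at <- pos + 8L
      }
    } else {
      vr <- "UN"
      len <- read_uint32(bytes, pos + 4L)
      val_at <- pos + 8L
    }
    if (val_at + len - 1L > n) stopf("truncated DICOM element")
    key <- sprintf("%04x,%04x", group, element)
    out[[key]] <- list(vr = vr, value = bytes[seq.int(val_at, length.out = len)])
    if (key == "0002,0010")
      ts <- raw_to_trimmed_string(out[[key]]$value)
    pos <- val_at + len
  }
  out
}

raw_to_trimmed_string <- function(value) {
  sub("\\s+$", "", rawToChar(value[value != as.raw(0)]))
}

dcm_get_str <- function(ds, key, default = NULL) {
  el <- ds[[key]]
  if (is.null(el)) return(default)
  raw_to_trimmed_string(el$value)
}
dcm_get_num <- function(ds, key, default = NULL) {
  s <- dcm_get_str(ds, key)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_get_us <- function(ds, key, default = NULL) {
  el <- ds[[key]]
  if (is.null(el)) return(default)
  if (el$vr %in% c("US", "UN")) read_uint16(el$value, 1L)
  else as.integer(dcm_get_num(ds, key, default))
}

#' Read a single-frame DICOM file into raw stored values plus metadata
#'
#' @param path file path.
#' @return list with `stored` (integer matrix, R column-major after
#'   transposing DICOM row order), `slope`, `intercept`, `modality`,
#'   `pixel_spacing_mm`, `patient_id`.
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  bytes <- readBin(path, raw(), n = file.size(path))
  ds <- dcm_parse(bytes)
  rows <- dcm_get_us(ds, "0028,0010")
  cols <- dcm_get_us(ds, "0028,0011")
  bits <- dcm_get_us(ds, "0028,0100", 16L)
  pixrep <- dcm_get_us(ds, "0028,0103", 0L)
  px <- ds[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stopf("DICOM file lacks Rows/Columns/PixelData: %s", path)
  if (bits != 16L) stopf("only 16-bit DICOM pixel data is supported")
  vals <- readBin(px$value, integer(), n = rows * cols, size = 2,
                  endian = "little", signed = FALSE)
  if (pixrep == 1L) vals <- ifelse(vals >= 32768L, vals - 65536L, vals)
  list(
    stored = t(matrix(as.integer(vals), nrow = cols, ncol = rows)),
    slope = dcm_get_num(ds, "0028,1053"),
    intercept = dcm_get_num(ds, "0028,1052"),
    modality = dcm_get_str(ds, "0008,0060", "UN"),
    pixel_spacing_mm = dcm_get_num(ds, "0028,0030"),
    patient_id = dcm_get_str(ds, "0010,0020", "")
  )
}
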