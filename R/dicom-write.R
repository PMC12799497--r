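# Minimal DICOM Part-10 serializer: explicit VR little endian, defined-length
# elements, single-frame CT slices. Scope is deliberately narrow — enough to
# write standard-conformant axial CT series (and to re-serialize datasets
# after de-identification), not a general DICOM toolkit.

DICOM_TRANSFER_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_TRANSFER_IMPLICIT_LE <- "1.2.840.10008.1.2"
DICOM_SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"
DICOM_UID_ROOT <- "1.2.826.0.1.3680043.10000"

# VRs whose explicit form uses a 2-byte reserved field and a 4-byte length.
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
STRING_VRS <- c(
  "AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
  "PN", "SH", "ST", "TM", "UI", "UT"
)

dcm_element <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

uint16_le <- function(x) {
  x <- as.integer(x)
  as.raw(c(rbind(x %% 256L, x %/% 256L)))
}

uint32_le <- function(x) {
  x <- as.double(x)
  as.raw(c(
    x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256
  ))
}

int16_le <- function(x) {
  x <- as.integer(round(x))
  if (any(x < -32768 | x > 32767)) {
    abort("Stored pixel values exceed the signed 16-bit range.")
  }
  writeBin(x, raw(), size = 2, endian = "little")
}

encode_value <- function(vr, value) {
  if (is.raw(value)) {
    out <- value
  } else if (vr %in% c("US")) {
    out <- uint16_le(value)
  } else if (vr %in% c("UL")) {
    out <- uint32_le(value)
  } else if (vr %in% STRING_VRS) {
    s <- if (vr %in% c("DS", "IS")) {
      paste(vapply(value, function(v) format(v, scientific = FALSE, trim = TRUE), ""),
        collapse = "\\"
      )
    } else {
      paste(as.character(value), collapse = "\\")
    }
    out <- charToRaw(s)
  } else {
    abort(sprintf("Cannot encode VR %s.", vr))
  }
  if (length(out) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    out <- c(out, pad)
  }
  out
}

encode_element <- function(el) {
  bytes <- encode_value(el$vr, el$value)
  head <- c(uint16_le(el$group), uint16_le(el$element), charToRaw(el$vr))
  if (el$vr %in% LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), uint32_le(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534) abort("Value too long for a short-form VR.")
    c(head, uint16_le(length(bytes)), bytes)
  }
}

# Serialize a parsed dataset (list of dcm_element, data-set part only) to a
# Part-10 file, regenerating the file meta group from the dataset's SOP
# identifiers.
write_dicom_dataset <- function(elements, path) {
  keys <- vapply(elements, function(e) tag_key(e$group, e$element), "")
  ord <- order(
    vapply(elements, `[[`, 0L, "group"),
    vapply(elements, `[[`, 0L, "element")
  )
  elements <- elements[ord]
  keys <- keys[ord]
  sop_uid <- elements[[match("0008,0018", keys)]]$value
  meta <- list(
    dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002L, 0x0002L, "UI", DICOM_SOP_CLASS_CT),
    dcm_element(0x0002L, 0x0003L, "UI", sop_uid),
    dcm_element(0x0002L, 0x0010L, "UI", DICOM_TRANSFER_EXPLICIT_LE),
    dcm_element(0x0002L, 0x0012L, "UI", paste0(DICOM_UID_ROOT, ".1"))
  )
  meta_bytes <- unlist(lapply(meta, encode_element))
  body <- unlist(lapply(elements, encode_element))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(encode_element(
    dcm_element(0x0002L, 0x0000L, "UL", length(meta_bytes))
  ), con)
  writeBin(meta_bytes, con)
  writeBin(body, con)
  invisible(path)
}

build_slice_dataset <- function(stored, z_index, z_pos, volume, patient,
                                series_uid, study_uid, slope, intercept) {
  spacing <- volume$spacing
  meta <- volume$meta
  els <- list(
    dcm_element(0x0008L, 0x0016L, "UI", DICOM_SOP_CLASS_CT),
    dcm_element(0x0008L, 0x0018L, "UI", paste0(series_uid, ".", z_index)),
    dcm_element(0x0008L, 0x0060L, "CS", "CT"),
    dcm_element(0x0008L, 0x0070L, "LO", meta$manufacturer %||% "SYNTHETIC"),
    dcm_element(0x0008L, 0x0080L, "LO", patient$institution %||% "PHANTOM LAB"),
    dcm_element(0x0008L, 0x0090L, "PN", patient$referring_physician %||% "REF^PHYS"),
    dcm_element(0x0010L, 0x0010L, "PN", patient$name %||% "PHANTOM^CASE"),
    dcm_element(0x0010L, 0x0020L, "LO", patient$id %||% "PHANTOM-0001"),
    dcm_element(0x0010L, 0x0030L, "DA", patient$birth_date %||% "19500101"),
    dcm_element(0x0020L, 0x000DL, "UI", study_uid),
    dcm_element(0x0020L, 0x000EL, "UI", series_uid),
    dcm_element(0x0020L, 0x0013L, "IS", z_index),
    dcm_element(0x0020L, 0x0032L, "DS", c(0, 0, z_pos)),
    dcm_element(0x0020L, 0x0037L, "DS", c(1, 0, 0, 0, 1, 0)),
    dcm_element(0x0018L, 0x0050L, "DS", meta$slice_thickness_mm %||% spacing[1]),
    dcm_element(0x0028L, 0x0002L, "US", 1L),
    dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dcm_element(0x0028L, 0x0010L, "US", nrow(stored)),
    dcm_element(0x0028L, 0x0011L, "US", ncol(stored)),
    dcm_element(0x0028L, 0x0030L, "DS", c(spacing[2], spacing[3])),
    dcm_element(0x0028L, 0x0100L, "US", 16L),
    dcm_element(0x0028L, 0x0101L, "US", 16L),
    dcm_element(0x0028L, 0x0102L, "US", 15L),
    dcm_element(0x0028L, 0x0103L, "US", 1L),
    dcm_element(0x0028L, 0x1052L, "DS", intercept),
    dcm_element(0x0028L, 0x1053L, "DS", slope),
    dcm_element(
      0x7FE0L, 0x0010L, "OW",
      int16_le(as.vector(t(stored))) # row-major pixel order
    )
  )
  age <- patient$age_years %||% volume$meta$age_years
  if (!is.null(age)) {
    els <- c(els, list(
      dcm_element(0x0010L, 0x1010L, "AS", sprintf("%03dY", as.integer(age)))
    ))
  }
  els
}

#' Write a CT volume as a DICOM series
#'
#' One Part-10 file per axial slice (explicit VR little endian, signed 16-bit
#' stored pixels) with consistent series identifiers, positions, spacing and
#' rescale calibration, such that [load_series()] round-trips the volume
#' within integer-storage quantization. Deterministic: the same volume and
#' arguments produce byte-identical files.
#'
#' @param volume A [ct_volume()].
#' @param directory Output directory (created if needed).
#' @param patient Named list of demographic entries (`name`, `id`,
#'   `birth_date`, `age_years`, `institution`, `referring_physician`);
#'   defaults are synthetic placeholders.
#' @param series_number Integer distinguishing series UIDs across cases.
#' @param slope,intercept Rescale calibration written to each slice; stored
#'   value = `round((HU - intercept) / slope)`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_dicom_series <- function(volume, directory, patient = list(),
                               series_number = 1L, slope = 1, intercept = -1024) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  d <- dim(volume$voxels)
  series_uid <- paste0(DICOM_UID_ROOT, ".2.", as.integer(series_number))
  study_uid <- paste0(DICOM_UID_ROOT, ".3.", as.integer(series_number))
  paths <- character(d[1])
  for (z in seq_len(d[1])) {
    stored <- round((volume$voxels[z, , ] - intercept) / slope)
    els <- build_slice_dataset(
      stored, z, (z - 1) * volume$spacing[1], volume, patient,
      series_uid, study_uid, slope, intercept
    )
    paths[z] <- file.path(directory, sprintf("slice_%04d.dcm", z))
    write_dicom_dataset(els, paths[z])
  }
  invisible(paths)
}
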