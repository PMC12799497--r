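# Minimal DICOM Part-10 parser: explicit and implicit VR little endian,
# defined-length elements only (an undefined-length sequence is rejected).
# Covers single-frame axial CT slices as produced by common scanners and by
# write_dicom_series().

# Tag dictionary used to resolve VRs under implicit VR little endian and to
# name parsed elements. Unknown tags fall back to UN (kept as raw bytes).
DICOM_DICT <- local({
  d <- rbind(
    c("0008,0016", "UI", "sop_class_uid"),
    c("0008,0018", "UI", "sop_instance_uid"),
    c("0008,0060", "CS", "modality"),
    c("0008,0070", "LO", "manufacturer"),
    c("0008,0080", "LO", "institution_name"),
    c("0008,0090", "PN", "referring_physician"),
    c("0010,0010", "PN", "patient_name"),
    c("0010,0020", "LO", "patient_id"),
    c("0010,0030", "DA", "patient_birth_date"),
    c("0010,1000", "LO", "other_patient_ids"),
    c("0010,1010", "AS", "patient_age"),
    c("0010,1040", "LO", "patient_address"),
    c("0010,4000", "LT", "patient_comments"),
    c("0018,0050", "DS", "slice_thickness"),
    c("0020,000D", "UI", "study_uid"),
    c("0020,000E", "UI", "series_uid"),
    c("0020,0013", "IS", "instance_number"),
    c("0020,0032", "DS", "image_position"),
    c("0020,0037", "DS", "image_orientation"),
    c("0028,0002", "US", "samples_per_pixel"),
    c("0028,0004", "CS", "photometric"),
    c("0028,0010", "US", "rows"),
    c("0028,0011", "US", "columns"),
    c("0028,0030", "DS", "pixel_spacing"),
    c("0028,0100", "US", "bits_allocated"),
    c("0028,0101", "US", "bits_stored"),
    c("0028,0102", "US", "high_bit"),
    c("0028,0103", "US", "pixel_representation"),
    c("0028,1052", "DS", "rescale_intercept"),
    c("0028,1053", "DS", "rescale_slope"),
    c("7FE0,0010", "OW", "pixel_data")
  )
  data.frame(tag = d[, 1], vr = d[, 2], name = d[, 3])
})

read_u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}

read_u32 <- function(bytes, pos) {
  as.double(as.integer(bytes[pos])) +
    256 * as.double(as.integer(bytes[pos + 1L])) +
    65536 * as.double(as.integer(bytes[pos + 2L])) +
    16777216 * as.double(as.integer(bytes[pos + 3L]))
}

decode_value <- function(vr, bytes) {
  if (vr %in% c("OB", "OW", "UN", "SQ", "OF")) {
    return(bytes)
  }
  if (vr == "US") {
    if (length(bytes) == 0) return(integer())
    n <- length(bytes) / 2
    return(vapply(seq_len(n), function(i) read_u16(bytes, 2L * i - 1L), 0L))
  }
  if (vr == "UL") {
    if (length(bytes) == 0) return(numeric())
    n <- length(bytes) / 4
    return(vapply(seq_len(n), function(i) read_u32(bytes, 4L * i - 3L), 0))
  }
  s <- rawToChar(bytes[bytes != as.raw(0L)])
  s <- sub("[ ]+$", "", s)
  if (vr %in% c("DS", "IS")) {
    if (!nzchar(s)) return(numeric())
    return(as.numeric(strsplit(s, "\\\\")[[1]]))
  }
  s
}

parse_elements <- function(bytes, pos, explicit, stop_before_group = NULL) {
  out <- list()
  n <- length(bytes)
  while (pos <= n - 7L) {
    group <- read_u16(bytes, pos)
    element <- read_u16(bytes, pos + 2L)
    if (!is.null(stop_before_group) && group != stop_before_group) break
    if (explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- read_u32(bytes, pos + 8L)
        data_pos <- pos + 12L
      } else {
        len <- read_u16(bytes, pos + 6L)
        data_pos <- pos + 8L
      }
    } else {
      key <- tag_key(group, element)
      hit <- match(key, DICOM_DICT$tag)
      vr <- if (is.na(hit)) "UN" else DICOM_DICT$vr[hit]
      len <- read_u32(bytes, pos + 4L)
      data_pos <- pos + 8L
    }
    if (len == 4294967295) {
      abort("Undefined-length DICOM elements (nested sequences) are not supported.")
    }
    if (data_pos + len - 1L > n) abort("Truncated DICOM element.")
    value_bytes <- if (len > 0) bytes[data_pos:(data_pos + len - 1L)] else raw(0)
    out[[length(out) + 1L]] <- dcm_element(
      group, element, vr, decode_value(vr, value_bytes)
    )
    pos <- data_pos + len
  }
  list(elements = out, pos = pos)
}

#' Read one DICOM file
#'
#' Parses a Part-10 file (explicit or implicit VR little endian) into a flat
#' list of elements. Intended for single-frame CT slices; undefined-length
#' sequences are rejected.
#'
#' @param path Path to a DICOM file.
#' @return A `dicom_dataset`: list with `elements` (parsed data-set elements)
#'   and `transfer_syntax`. Use [dcm_value()] to pull a value by name.
#' @export
read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    abort(sprintf("Not a DICOM Part-10 file: %s", path))
  }
  meta <- parse_elements(bytes, 133L, explicit = TRUE, stop_before_group = 0x0002L)
  ts <- DICOM_TRANSFER_EXPLICIT_LE
  for (el in meta$elements) {
    if (el$group == 0x0002L && el$element == 0x0010L) ts <- el$value
  }
  explicit <- ts != DICOM_TRANSFER_IMPLICIT_LE
  body <- parse_elements(bytes, meta$pos, explicit = explicit)
  structure(
    list(elements = body$elements, transfer_syntax = ts, path = path),
    class = "dicom_dataset"
  )
}

#' Extract an element value from a parsed dataset
#'
#' @param ds A `dicom_dataset` from [read_dicom_file()].
#' @param name Dictionary name (e.g. `"rows"`, `"pixel_spacing"`) or a
#'   `"GGGG,EEEE"` tag key.
#' @param default Returned when the element is absent.
#' @return The parsed value.
#' @export
dcm_value <- function(ds, name, default = NULL) {
  hit <- match(name, DICOM_DICT$name)
  tag <- if (is.na(hit)) toupper(name) else DICOM_DICT$tag[hit]
  for (el in ds$elements) {
    if (tag_key(el$group, el$element) == tag) {
      return(el$value)
    }
  }
  default
}

decode_pixels <- function(ds) {
  rows <- dcm_value(ds, "rows")
  cols <- dcm_value(ds, "columns")
  bits <- dcm_value(ds, "bits_allocated", 16L)
  if (is.null(rows) || is.null(cols)) abort("Missing Rows/Columns.")
  if (bits != 16L) abort("Only 16-bit stored pixels are supported.")
  raw_px <- dcm_value(ds, "pixel_data")
  if (is.null(raw_px)) abort("Missing pixel data.")
  signed <- isTRUE(dcm_value(ds, "pixel_representation", 0L) == 1L)
  v <- readBin(raw_px, "integer",
    n = rows * cols, size = 2,
    signed = signed, endian = "little"
  )
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}

slice_normal <- function(iop) {
  r <- iop[1:3]
  c_ <- iop[4:6]
  c(
    r[2] * c_[3] - r[3] * c_[2],
    r[3] * c_[1] - r[1] * c_[3],
    r[1] * c_[2] - r[2] * c_[1]
  )
}

parse_age <- function(s) {
  if (is.null(s) || !is.character(s)) return(NULL)
  m <- regmatches(s, regexec("^([0-9]+)Y", s))[[1]]
  if (length(m) == 2) as.numeric(m[2]) else NULL
}

#' Load an axial DICOM series as a calibrated HU volume
#'
#' Reads every DICOM file in a directory, verifies that they form a single
#' consistent axial series, sorts slices by the projection of the image
#' position onto the slice normal (falling back to instance number when
#' positions are absent), applies the per-slice rescale calibration, and
#' assembles a [ct_volume()].
#'
#' @param directory Directory containing one DICOM series.
#' @return A [ct_volume()] with spacing `(dz, dy, dx)` in mm and metadata
#'   (`series_uid`, `slice_thickness_mm`, `manufacturer`, `age_years`).
#' @export
load_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) abort(sprintf("No files in %s", directory))
  slices <- lapply(files, read_dicom_file)

  uids <- vapply(slices, function(s) dcm_value(s, "series_uid", NA_character_), "")
  if (length(unique(uids)) != 1L) {
    abort(sprintf(
      "Directory mixes %d series identifiers; one series per directory.",
      length(unique(uids))
    ))
  }
  dims <- vapply(
    slices,
    function(s) c(dcm_value(s, "rows", NA_integer_), dcm_value(s, "columns", NA_integer_)),
    integer(2)
  )
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("Slices have inconsistent row/column dimensions.")
  }

  iop <- dcm_value(slices[[1]], "image_orientation", c(1, 0, 0, 0, 1, 0))
  normal <- slice_normal(iop)
  if (abs(normal[3]) < 0.999) {
    abort("Non-axial slice orientation; this loader only accepts axial series.")
  }

  pos <- vapply(slices, function(s) {
    ipp <- dcm_value(s, "image_position")
    if (is.null(ipp) || length(ipp) != 3) NA_real_ else sum(ipp * normal)
  }, 0)
  if (anyNA(pos)) {
    key <- vapply(
      slices,
      function(s) as.double(dcm_value(s, "instance_number", NA_real_)[1]), 0
    )
    if (anyNA(key)) abort("Slices lack both positions and instance numbers.")
  } else {
    key <- pos
  }
  dup <- duplicated(round(key, 4)) | duplicated(round(key, 4), fromLast = TRUE)
  if (any(dup)) {
    abort(sprintf(
      "Duplicate slice positions in: %s",
      paste(basename(files[dup]), collapse = ", ")
    ))
  }
  ord <- order(key)
  slices <- slices[ord]
  key <- key[ord]

  dz <- if (length(key) > 1 && !anyNA(pos)) {
    median(diff(key))
  } else {
    dcm_value(slices[[1]], "slice_thickness", 1)[1]
  }
  ps <- dcm_value(slices[[1]], "pixel_spacing", c(1, 1))

  nz <- length(slices)
  vox <- array(0, dim = c(nz, dims[1, 1], dims[2, 1]))
  for (z in seq_len(nz)) {
    s <- slices[[z]]
    slope <- dcm_value(s, "rescale_slope", 1)[1]
    intercept <- dcm_value(s, "rescale_intercept", 0)[1]
    vox[z, , ] <- decode_pixels(s) * slope + intercept
  }

  ct_volume(
    vox,
    spacing = c(dz, ps[1], ps[2]),
    meta = list(
      series_uid = uids[1],
      slice_thickness_mm = dcm_value(slices[[1]], "slice_thickness", NA_real_)[1],
      manufacturer = dcm_value(slices[[1]], "manufacturer", NA_character_),
      age_years = parse_age(dcm_value(slices[[1]], "patient_age")),
      n_files = nz
    )
  )
}

#' Default personal-information tag list
#'
#' A documented subset of the DICOM de-identification Basic Profile: patient
#' name and identifiers, birth date, address and comments, institution and
#' referring physician. Geometry, calibration and pixel data are never on
#' this list.
#'
#' @return Character vector of `"GGGG,EEEE"` tag keys.
#' @export
phi_tags <- function() {
  c(
    "0008,0080", # institution name
    "0008,0090", # referring physician
    "0010,0010", # patient name
    "0010,0020", # patient id
    "0010,0030", # birth date
    "0010,1000", # other patient ids
    "0010,1040", # address
    "0010,4000" # comments
  )
}

#' De-identify a DICOM dataset
#'
#' Blanks every element on the personal-information tag list (zero-length
#' value, keeping the element so type-2 attributes stay standard-conformant).
#' Absent tags are skipped; pixel data, geometry and calibration are
#' untouched. Idempotent.
#'
#' @param ds A `dicom_dataset` from [read_dicom_file()].
#' @param tags Tag keys to blank; defaults to [phi_tags()].
#' @return The de-identified `dicom_dataset`.
#' @export
anonymize <- function(ds, tags = phi_tags()) {
  ds$elements <- lapply(ds$elements, function(el) {
    if (tag_key(el$group, el$element) %in% tags) {
      el$value <- if (is.raw(el$value)) raw(0) else ""
    }
    el
  })
  ds
}

#' Re-serialize a parsed dataset to a DICOM file
#'
#' Writes the dataset back as explicit VR little endian. Used after
#' [anonymize()] to persist de-identified slices.
#'
#' @param ds A `dicom_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dicom_file <- function(ds, path) {
  write_dicom_dataset(ds$elements, path)
}
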