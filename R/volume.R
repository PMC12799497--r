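#' Calibrated CT volume
#'
#' Container for a 3D array of Hounsfield-unit (HU) values with voxel spacing
#' and series metadata. Voxels are indexed `[z, y, x]`: `z` runs along the
#' slice stack (inferior to superior for an axial series sorted by position),
#' `y` is the in-slice row (anterior to posterior), and `x` the in-slice
#' column (patient left-right); `x` is therefore the sagittal slice index.
#' Values are assumed rescale-calibrated (stored value times slope plus
#' intercept already applied).
#'
#' @param voxels 3D numeric array of HU values, dimensions `(nz, ny, nx)`.
#' @param spacing Numeric length-3 vector `(dz, dy, dx)` in mm, all positive.
#' @param meta Named list of series metadata. Recognised entries:
#'   `series_uid`, `slice_thickness_mm`, `manufacturer`, `age_years`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, meta = list()) {
  if (length(dim(voxels)) != 3) {
    abort("`voxels` must be a 3D array indexed [z, y, x].")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive values (dz, dy, dx) in mm.")
  }
  structure(
    list(voxels = voxels, spacing = spacing, meta = meta),
    class = "ct_volume"
  )
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d slices x %d rows x %d cols, spacing (%.3g, %.3g, %.3g) mm, HU range [%.0f, %.0f]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' Eligibility rule for opportunistic screening
#'
#' Cohort eligibility used before reconstruction: slices must be thin enough
#' for the sagittal reformat to resolve vertebral endplates, and the screening
#' population is the age group at fragility-fracture risk.
#'
#' @param max_slice_thickness_mm Maximum slice thickness in mm (default 3).
#' @param min_age_years Minimum subject age in years (default 50).
#' @return An `eligibility_rule` list.
#' @export
eligibility_rule <- function(max_slice_thickness_mm = 3, min_age_years = 50) {
  if (max_slice_thickness_mm <= 0 || min_age_years <= 0) {
    abort("Eligibility thresholds must be positive.")
  }
  structure(
    list(
      max_slice_thickness_mm = max_slice_thickness_mm,
      min_age_years = min_age_years
    ),
    class = "eligibility_rule"
  )
}

#' Check series eligibility
#'
#' A series is eligible when its slice thickness is at or below the rule's
#' maximum and the subject age, when known, is at or above the rule's minimum.
#' Missing thickness is conservative (ineligible with a reason); missing age
#' only concerns the cohort definition, not the algorithm, and does not block.
#'
#' @param meta Series metadata list (from [ct_volume()] or [load_series()]):
#'   uses `slice_thickness_mm` and optional `age_years`.
#' @param rule An [eligibility_rule()].
#' @return A list with `eligible` (logical) and `reasons` (character vector of
#'   failed rules, empty when eligible).
#' @export
check_eligibility <- function(meta, rule = eligibility_rule()) {
  reasons <- character()
  thick <- meta$slice_thickness_mm
  if (is.null(thick) || !is.finite(thick)) {
    reasons <- c(reasons, "slice thickness: missing")
  } else if (thick > rule$max_slice_thickness_mm) {
    reasons <- c(reasons, sprintf(
      "slice thickness: %.3g mm exceeds %.3g mm",
      thick, rule$max_slice_thickness_mm
    ))
  }
  age <- meta$age_years
  if (!is.null(age) && is.finite(age) && age < rule$min_age_years) {
    reasons <- c(reasons, sprintf(
      "age: %.3g years below %.3g years", age, rule$min_age_years
    ))
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}
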