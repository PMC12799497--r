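# Synthetic thoracolumbar CT phantom. Geometry is deliberately cuboid-based:
# vertebral bodies are cortical-shelled cuboids stacked along z with disc
# gaps, embedded in soft tissue over an air background. Ground truth is
# therefore exactly computable; nothing downstream depends on anatomical
# realism.

#' Phantom specification
#'
#' Defaults describe a plausible adult thoracolumbar segment on a routine
#' chest/abdominal protocol: 12 vertebrae of 25 mm height with 5 mm discs,
#' trabecular bone 250 HU inside a 900 HU cortical shell, 80 HU discs, 30 HU
#' soft tissue, air background, 1.5 mm slices with 0.8 mm in-plane pixels,
#' and 20 HU additive Gaussian noise.
#'
#' @param n_vertebrae Number of vertebrae (default 12).
#' @param vertebral_height_mm,disc_height_mm Body and disc heights in mm.
#' @param depth_mm,width_mm Vertebral body extent in y (anteroposterior) and
#'   x (lateral), mm.
#' @param trabecular_hu,cortical_hu,disc_hu,soft_tissue_hu,air_hu Tissue HU
#'   values; must be ordered air < soft tissue < disc < trabecular < cortical.
#' @param spine_plane_x Sagittal voxel column of the spine centre (1-based);
#'   `NULL` centres it.
#' @param scoliosis_offset_mm Amplitude of a sinusoidal lateral displacement
#'   of vertebral centres (default 0).
#' @param noise_sd Additive Gaussian noise SD in HU (default 20).
#' @param spacing Voxel spacing `(dz, dy, dx)` mm (default 1.5, 0.8, 0.8).
#' @param margin_z_mm,margin_y_mm,margin_x_mm Tissue margins around the spine.
#' @param process_depth_mm,process_halfwidth_mm Extent of the posterior
#'   midline element (pedicles/spinous process) behind each vertebral body.
#' @param age_years Subject age written to fixtures (default 72).
#' @param seed Integer seed; a fixed seed gives byte-identical volumes.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_vertebrae = 12, vertebral_height_mm = 25,
                         disc_height_mm = 5, depth_mm = 30, width_mm = 35,
                         trabecular_hu = 250, cortical_hu = 900, disc_hu = 80,
                         soft_tissue_hu = 30, air_hu = -1000,
                         spine_plane_x = NULL, scoliosis_offset_mm = 0,
                         noise_sd = 20, spacing = c(1.5, 0.8, 0.8),
                         margin_z_mm = 10, margin_y_mm = 30, margin_x_mm = 45,
                         process_depth_mm = 12, process_halfwidth_mm = 3,
                         age_years = 72, seed = 1L) {
  if (any(diff(c(air_hu, soft_tissue_hu, disc_hu, trabecular_hu, cortical_hu)) <= 0)) {
    abort("Tissue HU must satisfy air < soft tissue < disc < trabecular < cortical.")
  }
  structure(
    list(
      n_vertebrae = n_vertebrae, vertebral_height_mm = vertebral_height_mm,
      disc_height_mm = disc_height_mm, depth_mm = depth_mm, width_mm = width_mm,
      trabecular_hu = trabecular_hu, cortical_hu = cortical_hu, disc_hu = disc_hu,
      soft_tissue_hu = soft_tissue_hu, air_hu = air_hu,
      spine_plane_x = spine_plane_x, scoliosis_offset_mm = scoliosis_offset_mm,
      noise_sd = noise_sd, spacing = spacing, margin_z_mm = margin_z_mm,
      margin_y_mm = margin_y_mm, margin_x_mm = margin_x_mm,
      process_depth_mm = process_depth_mm,
      process_halfwidth_mm = process_halfwidth_mm,
      age_years = age_years, seed = seed
    ),
    class = "phantom_spec"
  )
}

FRACTURE_KINDS <- c("fracture_wedge", "fracture_biconcave", "fracture_crush")
MIMIC_KINDS <- c("oa_wedge", "short_vertebra")

#' Grade label from fractional height loss
#'
#' Height-loss bands anchor the semi-quantitative vocabulary: below 20 %
#' minimal, 20-25 % mild, 25-40 % moderate, above 40 % severe. Height losses
#' at or below 5 % are treated as no deformity (sub-voxel changes are not
#' generateable, let alone detectable).
#'
#' @param height_loss_fraction Fraction of vertebral height lost, in `[0, 1)`.
#' @return A grade label from [vf_grades()].
#' @export
grade_from_height_loss <- function(height_loss_fraction) {
  vapply(height_loss_fraction, function(h) {
    if (h <= 0.05) {
      "none"
    } else if (h < 0.20) {
      "minimal"
    } else if (h < 0.25) {
      "mild"
    } else if (h <= 0.40) {
      "moderate"
    } else {
      "severe"
    }
  }, "")
}

#' Specify a vertebral deformity
#'
#' Fracture kinds (`fracture_wedge`: anterior height loss; `fracture_biconcave`:
#' central endplate depression; `fracture_crush`: global collapse) carry a
#' grade from their height loss. Mimic kinds are label-negative:
#' `oa_wedge_pair` applies matched anterior wedging without endplate
#' depression to two adjacent vertebrae; `short_vertebra` applies uniform
#' height reduction with anteroposterior elongation.
#'
#' @param vertebra_index 1-based vertebra index (inferior to superior).
#' @param kind One of `"fracture_wedge"`, `"fracture_biconcave"`,
#'   `"fracture_crush"`, `"oa_wedge_pair"`, `"short_vertebra"`.
#' @param height_loss_fraction Fractional height loss in `[0, 1)`.
#' @return A one- or two-row deformity tibble (the OA pair expands to both
#'   affected vertebrae).
#' @export
deformity_spec <- function(vertebra_index, kind, height_loss_fraction) {
  kind <- match.arg(kind, c(FRACTURE_KINDS, "oa_wedge_pair", "short_vertebra"))
  if (height_loss_fraction < 0 || height_loss_fraction >= 1) {
    abort("height_loss_fraction must lie in [0, 1).")
  }
  if (kind == "oa_wedge_pair") {
    return(tibble(
      vertebra_index = c(vertebra_index, vertebra_index + 1L),
      kind = "oa_wedge", height_loss_fraction = height_loss_fraction,
      grade = "none"
    ))
  }
  grade <- if (kind %in% FRACTURE_KINDS) {
    grade_from_height_loss(height_loss_fraction)
  } else {
    "none"
  }
  tibble(
    vertebra_index = as.integer(vertebra_index), kind = kind,
    height_loss_fraction = height_loss_fraction, grade = grade
  )
}

height_loss_profile <- function(kind, hlf, t) {
  switch(kind,
    none = rep(0, length(t)),
    fracture_wedge = hlf * (1 - t),
    oa_wedge = hlf * (1 - t),
    fracture_biconcave = hlf * (1 - (2 * t - 1)^2),
    fracture_crush = rep(hlf, length(t)),
    short_vertebra = rep(hlf, length(t)),
    abort(sprintf("Unknown deformity kind: %s", kind))
  )
}

phantom_dims <- function(spec) {
  dz <- spec$spacing[1]
  dy <- spec$spacing[2]
  dx <- spec$spacing[3]
  pitch <- spec$vertebral_height_mm + spec$disc_height_mm
  nz <- max(2L, round((spec$n_vertebrae * pitch + 2 * spec$margin_z_mm) / dz))
  ny <- max(2L, round((spec$depth_mm + 2 * spec$margin_y_mm) / dy))
  nx <- if (is.null(spec$spine_plane_x)) {
    max(41L, round((spec$width_mm + 2 * spec$margin_x_mm) / dx))
  } else {
    max(
      41L, round((spec$width_mm + 2 * spec$margin_x_mm) / dx),
      spec$spine_plane_x + 5L
    )
  }
  list(
    nz = nz, ny = ny, nx = nx, pitch = pitch,
    spine_x = spec$spine_plane_x %||% as.integer(round(nx / 2))
  )
}

#' Compute phantom ground truth without materializing voxels
#'
#' The per-vertebra geometry and labels that [make_spine_volume()] realises
#' in voxels, computed directly — used for large simulated cohorts where the
#' voxel volumes themselves are not needed.
#'
#' @inheritParams make_spine_volume
#' @return A `vf_ground_truth`.
#' @export
make_ground_truth <- function(spec = phantom_spec(), deformities = NULL) {
  if (is.null(deformities)) {
    deformities <- deformity_spec(1L, "fracture_wedge", 0)[0, ]
  }
  if (nrow(deformities) && max(deformities$vertebra_index) > spec$n_vertebrae) {
    abort("Deformity index exceeds n_vertebrae.")
  }
  if (anyDuplicated(deformities$vertebra_index)) {
    abort("Overlapping deformities on one vertebra.")
  }
  dims <- phantom_dims(spec)
  spine_x_mm <- (dims$spine_x - 1) * spec$spacing[3]
  verts <- purrr::map(seq_len(spec$n_vertebrae), function(i) {
    hit <- which(deformities$vertebra_index == i)
    kind <- if (length(hit)) deformities$kind[hit] else "none"
    hlf <- if (length(hit)) deformities$height_loss_fraction[hit] else 0
    grade <- if (length(hit)) deformities$grade[hit] else "none"
    zb <- spec$margin_z_mm + (i - 1) * dims$pitch
    xc <- spine_x_mm + spec$scoliosis_offset_mm *
      sin(pi * (i - 0.5) / spec$n_vertebrae)
    depth <- spec$depth_mm * if (kind == "short_vertebra") 1.2 else 1
    y0 <- spec$margin_y_mm - (depth - spec$depth_mm) / 2
    tibble(
      index = i, kind = kind, grade = grade, height_loss_fraction = hlf,
      z0_mm = zb, z1_mm = zb + spec$vertebral_height_mm,
      y0_mm = y0, y1_mm = y0 + depth, x_c_mm = xc
    )
  })
  vertebrae <- dplyr::bind_rows(verts)
  structure(
    list(
      vertebrae = vertebrae,
      case_label = any(vertebrae$kind %in% FRACTURE_KINDS),
      spine_plane_x = dims$spine_x,
      spec = spec
    ),
    class = "vf_ground_truth"
  )
}

#' Generate a synthetic spine CT volume with ground truth
#'
#' Builds the phantom volume described by `spec`, applies the requested
#' deformities, adds Gaussian noise (seeded; ground truth records geometry
#' before noise), and returns both the volume and a ground-truth manifest.
#'
#' @param spec A [phantom_spec()].
#' @param deformities A deformity tibble — row-bind of [deformity_spec()]
#'   results — or `NULL` for a deformity-free spine.
#' @return List with `volume` (a [ct_volume()]) and `ground_truth` (a
#'   `vf_ground_truth`: per-vertebra records, case label, spec).
#' @export
make_spine_volume <- function(spec = phantom_spec(), deformities = NULL) {
  gt <- make_ground_truth(spec, deformities)
  dims <- phantom_dims(spec)
  dz <- spec$spacing[1]
  dy <- spec$spacing[2]
  dx <- spec$spacing[3]
  nz <- dims$nz
  ny <- dims$ny
  nx <- dims$nx
  z_mm <- (seq_len(nz) - 1) * dz
  y_mm <- (seq_len(ny) - 1) * dy
  x_mm <- (seq_len(nx) - 1) * dx

  vox <- array(spec$air_hu, dim = c(nz, ny, nx))
  # torso soft tissue: everything except a thin air rim
  rim_y <- max(1L, round(3 / dy))
  rim_x <- max(1L, round(3 / dx))
  vox[, (rim_y + 1L):(ny - rim_y), (rim_x + 1L):(nx - rim_x)] <- spec$soft_tissue_hu

  for (i in seq_len(spec$n_vertebrae)) {
    v <- gt$vertebrae[i, ]
    jj <- which(y_mm >= v$y0_mm & y_mm <= v$y1_mm)
    if (!length(jj)) next
    tt <- (y_mm[jj] - v$y0_mm) / (v$y1_mm - v$y0_mm)
    loss <- height_loss_profile(v$kind, v$height_loss_fraction, tt)
    for (a in seq_along(jj)) {
      # elliptical body cross-section: lateral half-width shrinks toward the
      # anterior/posterior ends, so no full-height cortical plane exists
      # off the midline
      half_w <- spec$width_mm / 2 *
        sqrt(pmax(0.04, 1 - (2 * tt[a] - 1)^2))
      ii <- which(abs(x_mm - v$x_c_mm) <= half_w)
      if (!length(ii)) next
      h_y <- spec$vertebral_height_mm * (1 - loss[a])
      kk <- which(z_mm >= v$z0_mm & z_mm <= v$z0_mm + h_y)
      if (!length(kk)) next
      vox[kk, jj[a], ii] <- spec$trabecular_hu
      # cortical shell: endplates and local lateral rim
      vox[c(kk[1], kk[length(kk)]), jj[a], ii] <- spec$cortical_hu
      vox[kk, jj[a], c(ii[1], ii[length(ii)])] <- spec$cortical_hu
    }
    # posterior midline element (pedicles/spinous process): depth tapers away
    # from the midline, so the sagittal HU-sum profile peaks strictly at the
    # mid-spine plane as real posterior elements make it do
    kk_s <- which(z_mm >= v$z0_mm + 2 & z_mm <= v$z1_mm - 2)
    ii_s <- which(abs(x_mm - v$x_c_mm) <= spec$process_halfwidth_mm)
    if (length(kk_s)) {
      for (b in ii_s) {
        taper <- 1 - abs(x_mm[b] - v$x_c_mm) / spec$process_halfwidth_mm
        jj_s <- which(y_mm > v$y1_mm &
          y_mm <= v$y1_mm + spec$process_depth_mm * taper)
        if (length(jj_s)) vox[kk_s, jj_s, b] <- spec$cortical_hu
      }
    }
    # intervertebral disc above the nominal endplate
    if (i < spec$n_vertebrae) {
      kk_d <- which(z_mm > v$z1_mm & z_mm < v$z0_mm + dims$pitch)
      jj_d <- which(y_mm >= spec$margin_y_mm &
        y_mm <= spec$margin_y_mm + spec$depth_mm)
      ii_d <- which(abs(x_mm - v$x_c_mm) <= spec$width_mm / 2)
      if (length(kk_d) && length(jj_d)) vox[kk_d, jj_d, ii_d] <- spec$disc_hu
    }
  }

  if (spec$noise_sd > 0) {
    vox <- vox + with_seed(
      spec$seed,
      array(rnorm(length(vox), 0, spec$noise_sd), dim = dim(vox))
    )
  }

  volume <- ct_volume(
    vox,
    spacing = spec$spacing,
    meta = list(
      slice_thickness_mm = dz, manufacturer = "SYNTHETIC",
      age_years = spec$age_years, spine_plane_x = dims$spine_x
    )
  )
  list(volume = volume, ground_truth = gt)
}

#' @export
print.vf_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<vf_ground_truth> %d vertebrae, case %s\n",
    nrow(x$vertebrae), if (x$case_label) "VF-positive" else "VF-negative"
  ))
  def <- x$vertebrae[x$vertebrae$kind != "none", ]
  if (nrow(def)) print(def[, c("index", "kind", "grade", "height_loss_fraction")])
  invisible(x)
}

#' Project ground-truth vertebra extents into CSR image coordinates
#'
#' Maps each vertebra's physical (z, y) extent through the head-up flip and
#' isotropic resampling recorded in a reconstructed slab, yielding 0-based
#' pixel boxes in the CSR frame (the frame detector boxes are reported in).
#'
#' @param gt A `vf_ground_truth` from [make_spine_volume()].
#' @param slab The `csr_image` reconstructed from the same volume.
#' @param fractures_only Keep only fracture-kind vertebrae (default `TRUE`).
#' @return A box tibble with an extra `vertebra` column (`confidence` set
#'   to 1).
#' @export
gt_boxes_csr <- function(gt, slab, fractures_only = TRUE) {
  v <- gt$vertebrae
  if (fractures_only) v <- v[v$kind %in% FRACTURE_KINDS, ]
  rs <- slab$pixel_spacing[1]
  cs <- slab$pixel_spacing[2]
  z_top_mm <- (nrow(slab$pixels) - 1) * rs
  b <- tibble(
    top = (z_top_mm - v$z1_mm) / rs,
    left = v$y0_mm / cs,
    height = (v$z1_mm - v$z0_mm) / rs,
    width = (v$y1_mm - v$y0_mm) / cs,
    confidence = 1,
    vertebra = v$index
  )
  b[b$height > 0 & b$width > 0, ]
}

#' Map boxes from original CSR coordinates into the standardized frame
#'
#' Forward companion of [map_boxes_back()].
#'
#' @param boxes Box tibble in original image coordinates.
#' @param transform A `standardization_transform` from [standardize_512()].
#' @return The translated box tibble.
#' @export
map_boxes_forward <- function(boxes, transform) {
  dplyr::mutate(
    boxes,
    top = .data$top - transform$crop[["row"]] + transform$pad_before[["row"]],
    left = .data$left - transform$crop[["col"]] + transform$pad_before[["col"]]
  )
}

#' Write a phantom case as a DICOM fixture with a ground-truth manifest
#'
#' One DICOM series directory per case plus a `manifest.json` holding the
#' per-vertebra ground truth, the case label and the case seed, so that a
#' batch run can replay the oracle detector against it.
#'
#' @param volume A [ct_volume()] from [make_spine_volume()].
#' @param gt The matching `vf_ground_truth`.
#' @param directory Case directory to create.
#' @param series_number Series number for UID generation.
#' @return Invisibly, `directory`.
#' @export
write_case_fixture <- function(volume, gt, directory, series_number = 1L) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  write_dicom_series(
    volume, file.path(directory, "dicom"),
    patient = list(age_years = volume$meta$age_years),
    series_number = series_number
  )
  manifest <- list(
    case_label = gt$case_label,
    spine_plane_x = gt$spine_plane_x,
    seed = gt$spec$seed,
    vertebrae = gt$vertebrae
  )
  jsonlite::write_json(
    manifest, file.path(directory, "manifest.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(directory)
}

#' Read a ground-truth manifest written by [write_case_fixture()]
#'
#' @param path Path to a `manifest.json` (or the case directory containing it).
#' @return A `vf_ground_truth`.
#' @export
read_case_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      vertebrae = as_tibble(m$vertebrae),
      case_label = isTRUE(m$case_label),
      spine_plane_x = m$spine_plane_x,
      spec = list(seed = m$seed)
    ),
    class = "vf_ground_truth"
  )
}
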