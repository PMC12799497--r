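#' Display window for CT preprocessing
#'
#' HU clamp applied before projection. A wide bone-type window (width 1500 HU
#' centred at 300 HU, i.e. bounds \[-450, 1050\]) keeps trabecular and
#' cortical bone contrast while capping metal/contrast extremes, and makes the
#' sagittal HU-sum profile bone-dominated so the mid-spine plane wins the
#' argmax.
#'
#' @param width Window width in HU (> 0). Default 1500.
#' @param level Window centre in HU. Default 300.
#' @return A `window_settings` list with `width`, `level`, `lower`, `upper`.
#' @export
window_settings <- function(width = 1500, level = 300) {
  if (width <= 0) abort("Window width must be positive.")
  structure(
    list(
      width = width, level = level,
      lower = level - width / 2, upper = level + width / 2
    ),
    class = "window_settings"
  )
}

#' Clamp a volume to a display window
#'
#' Every voxel is clamped to `[level - width/2, level + width/2]`. Idempotent.
#'
#' @param volume A [ct_volume()].
#' @param w A [window_settings()].
#' @return A `ct_volume` with clamped voxels.
#' @export
apply_window <- function(volume, w = window_settings()) {
  volume$voxels <- pmin(pmax(volume$voxels, w$lower), w$upper)
  volume$meta$window <- c(width = w$width, level = w$level)
  volume
}

#' Sagittal HU-sum profile
#'
#' Sum of all HU values in each sagittal (fixed-`x`) plane. Bone is by far
#' the brightest tissue on CT, so the profile peaks at the mid-spine plane.
#'
#' @param volume A (typically windowed) [ct_volume()].
#' @return Numeric vector of length `dim(volume)[3]`; element `x` is the sum
#'   of `voxels[, , x]`.
#' @export
sagittal_sum_profile <- function(volume) {
  v <- volume$voxels
  d <- dim(v)
  dim(v) <- c(d[1] * d[2], d[3])
  colSums(v)
}

#' Central sagittal slice index
#'
#' Index of the profile maximum — the mid-spine sagittal plane. Ties are
#' broken by the smallest index for determinism.
#'
#' @param profile Numeric vector from [sagittal_sum_profile()].
#' @return Integer index in `1..length(profile)` (R 1-based).
#' @export
central_index <- function(profile) {
  if (length(profile) == 0) abort("Profile is empty.")
  which.max(profile)
}

new_csr_image <- function(pixels, central_index, half_width, pixel_spacing,
                          n_slices, eightbit = FALSE, transforms = character(),
                          window = NULL) {
  structure(
    list(
      pixels = pixels, central_index = central_index, half_width = half_width,
      pixel_spacing = pixel_spacing, n_slices = n_slices, eightbit = eightbit,
      transforms = transforms, window = window
    ),
    class = "csr_image"
  )
}

#' @export
dim.csr_image <- function(x) dim(x$pixels)

#' @export
print.csr_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<csr_image%s> %d x %d, central slice %d, half-width %d (%d slices summed), spacing (%.3g, %.3g) mm\n",
    if (x$eightbit) " 8-bit" else " raw", d[1], d[2],
    x$central_index, x$half_width, x$n_slices,
    x$pixel_spacing[1], x$pixel_spacing[2]
  ))
  if (length(x$transforms)) cat("  transforms:", paste(x$transforms, collapse = " -> "), "\n")
  invisible(x)
}

slab_range <- function(nx, centre, half_width) {
  if (half_width < 0) abort("`half_width` must be non-negative.")
  if (centre < 1 || centre > nx) abort("Central index outside the volume.")
  c(max(1L, centre - half_width), min(nx, centre + half_width))
}

#' Central slab projection (CSR)
#'
#' Sums the `2 * half_width + 1` sagittal slices centred on `centre`
#' (inclusive bounds; 41 slices at the default half-width of 20 when the slab
#' is interior). At the volume border only the existing slices are summed —
#' no reflection and no renormalisation, since the downstream min-max 8-bit
#' map absorbs the scale.
#'
#' @param volume A windowed [ct_volume()].
#' @param centre 1-based sagittal slice index, usually from [central_index()].
#' @param half_width Slices on each side of the centre (default 20).
#' @return A raw (not yet 8-bit) `csr_image`; rows are the volume's `z` axis,
#'   columns its `y` axis; `n_slices` records the effective slab size after
#'   border clamping.
#' @export
csr_project <- function(volume, centre, half_width = 20) {
  d <- dim(volume$voxels)
  r <- slab_range(d[3], centre, half_width)
  px <- rowSums(volume$voxels[, , r[1]:r[2], drop = FALSE], dims = 2)
  new_csr_image(
    px, centre, half_width,
    pixel_spacing = c(volume$spacing[1], volume$spacing[2]),
    n_slices = r[2] - r[1] + 1L,
    transforms = sprintf("csr_project[x %d..%d]", r[1], r[2]),
    window = volume$meta$window
  )
}

#' Maximum intensity projection over the same slab
#'
#' Per-pixel maximum over the slab window, the conventional comparator to the
#' central-slab sum.
#'
#' @inheritParams csr_project
#' @return A raw `csr_image` of per-pixel maxima.
#' @export
mip_project <- function(volume, centre, half_width = 20) {
  d <- dim(volume$voxels)
  r <- slab_range(d[3], centre, half_width)
  px <- Reduce(pmax, lapply(r[1]:r[2], function(k) volume$voxels[, , k]))
  new_csr_image(
    px, centre, half_width,
    pixel_spacing = c(volume$spacing[1], volume$spacing[2]),
    n_slices = r[2] - r[1] + 1L,
    transforms = sprintf("mip_project[x %d..%d]", r[1], r[2]),
    window = volume$meta$window
  )
}

#' Single sagittal slice (MPR)
#'
#' The single-voxel-thick sagittal plane at `centre` — the degenerate slab.
#'
#' @inheritParams csr_project
#' @return A raw `csr_image` with `half_width = 0`.
#' @export
mpr_slice <- function(volume, centre) {
  csr_project(volume, centre, half_width = 0L)
}

#' Resample slab rows to isotropic pixels
#'
#' CT slice spacing (image rows after reformatting) usually differs from the
#' in-plane spacing (columns); displaying the raw matrix would distort
#' vertebral heights. Rows are linearly interpolated so that mm/row equals
#' mm/column, preserving the physical extent.
#'
#' @param slab A `csr_image`.
#' @return A `csr_image` with equal row and column spacing; identity when the
#'   input is already isotropic.
#' @export
resample_isotropic <- function(slab) {
  dz <- slab$pixel_spacing[1]
  dy <- slab$pixel_spacing[2]
  if (isTRUE(all.equal(dz, dy))) {
    return(slab)
  }
  n <- nrow(slab$pixels)
  extent <- (n - 1) * dz
  n_out <- max(2L, as.integer(round(extent / dy)) + 1L)
  old_pos <- seq(0, extent, length.out = n)
  new_pos <- seq(0, extent, length.out = n_out)
  px <- apply(slab$pixels, 2, function(col) {
    approx(old_pos, col, xout = new_pos, method = "linear")$y
  })
  slab$pixels <- px
  slab$pixel_spacing <- c(extent / (n_out - 1), dy)
  slab$transforms <- c(
    slab$transforms,
    sprintf("resample_isotropic[%d->%d rows]", n, n_out)
  )
  slab
}

#' Convert a raw slab to an 8-bit image
#'
#' Linear min-max map onto 0..255 with half-up rounding. A constant slab
#' carries no contrast and maps to all zeros rather than raising an error.
#'
#' @param slab A raw `csr_image`.
#' @return An 8-bit `csr_image` (integer pixels in 0..255).
#' @export
normalize_to_8bit <- function(slab) {
  px <- slab$pixels
  lo <- min(px)
  hi <- max(px)
  if (hi > lo) {
    px <- round_half_up((px - lo) / (hi - lo) * 255)
  } else {
    px <- array(0, dim = dim(px))
  }
  storage.mode(px) <- "integer"
  slab$pixels <- px
  slab$eightbit <- TRUE
  slab$transforms <- c(slab$transforms, "normalize_to_8bit")
  slab
}

orient_head_up <- function(slab) {
  slab$pixels <- slab$pixels[rev(seq_len(nrow(slab$pixels))), , drop = FALSE]
  slab$transforms <- c(slab$transforms, "orient_head_up")
  slab
}

#' Full sagittal central-slab reconstruction
#'
#' The composite pipeline: window clamp, sagittal HU-sum profile, central
#' slice selection, slab summation, head-up orientation (rows run superior to
#' inferior, columns anterior to posterior), isotropic row resampling, and
#' 8-bit min-max conversion.
#'
#' @param volume A [ct_volume()] straight from [load_series()] or
#'   [make_spine_volume()].
#' @param w A [window_settings()].
#' @param half_width Slab half-width in slices (default 20).
#' @param profile_on `"windowed"` (default) computes the slice-sum profile on
#'   the clamped volume; `"raw"` uses unclamped HU.
#' @param mode `"csr"` (default), `"mip"`, or `"mpr"` — which projection fills
#'   the slab.
#' @return An 8-bit `csr_image`.
#' @export
reconstruct_csr <- function(volume, w = window_settings(), half_width = 20,
                            profile_on = c("windowed", "raw"),
                            mode = c("csr", "mip", "mpr")) {
  profile_on <- match.arg(profile_on)
  mode <- match.arg(mode)
  windowed <- apply_window(volume, w)
  prof <- sagittal_sum_profile(if (profile_on == "windowed") windowed else volume)
  c_idx <- central_index(prof)
  slab <- switch(mode,
    csr = csr_project(windowed, c_idx, half_width),
    mip = mip_project(windowed, c_idx, half_width),
    mpr = mpr_slice(windowed, c_idx)
  )
  normalize_to_8bit(resample_isotropic(orient_head_up(slab)))
}

#' Plot a CSR image
#'
#' Grey-scale raster of the slab with anatomical axes (rows superior to
#' inferior, columns anterior to posterior after [reconstruct_csr()]).
#'
#' @param object A `csr_image`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.csr_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$value <- px[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(ratio = object$pixel_spacing[1] / object$pixel_spacing[2]) +
    ggplot2::labs(x = "anterior → posterior (px)", y = "superior → inferior (px)") +
    ggplot2::theme_minimal()
}
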