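# 512 x 512 standardization for the detector input: larger images are
# center-cropped (the spine sits mid-frame by construction of the central
# slab), smaller ones zero-padded symmetrically with the odd remainder going
# to the bottom/right.

axis_transform <- function(n, size) {
  if (n >= size) {
    list(crop = floor((n - size) / 2), pad_before = 0L, pad_after = 0L)
  } else {
    total <- size - n
    list(crop = 0L, pad_before = floor(total / 2), pad_after = ceiling(total / 2))
  }
}

#' Standardize an image to the detector's 512 x 512 frame
#'
#' Per axis: center crop when larger than `size`, symmetric zero-pad when
#' smaller (extra pixel to the bottom/right on an odd remainder). The
#' returned transform maps coordinates between the original and the
#' standardized frame and is invertible for content inside the retained
#' region.
#'
#' @param image Integer matrix (8-bit) or `csr_image`.
#' @param size Target side length (default 512).
#' @return List with `image` (`size` x `size` matrix) and `transform` (a
#'   `standardization_transform`: crop offsets, pad amounts, original size;
#'   all 0-based pixel offsets).
#' @export
standardize_512 <- function(image, size = 512L) {
  if (inherits(image, "csr_image")) image <- image$pixels
  n <- dim(image)
  tr_r <- axis_transform(n[1], size)
  tr_c <- axis_transform(n[2], size)
  out <- matrix(0L, size, size)
  src_rows <- (tr_r$crop + 1L):min(n[1], tr_r$crop + size)
  src_cols <- (tr_c$crop + 1L):min(n[2], tr_c$crop + size)
  dst_rows <- (tr_r$pad_before + 1L):(tr_r$pad_before + length(src_rows))
  dst_cols <- (tr_c$pad_before + 1L):(tr_c$pad_before + length(src_cols))
  out[dst_rows, dst_cols] <- image[src_rows, src_cols]
  transform <- structure(
    list(
      crop = c(row = tr_r$crop, col = tr_c$crop),
      pad_before = c(row = tr_r$pad_before, col = tr_c$pad_before),
      pad_after = c(row = tr_r$pad_after, col = tr_c$pad_after),
      original = c(row = n[1], col = n[2]),
      size = size
    ),
    class = "standardization_transform"
  )
  list(image = out, transform = transform)
}

#' Map detector boxes back to original image coordinates
#'
#' Inverse of the [standardize_512()] coordinate map. Boxes lying entirely in
#' a zero-padded margin have no pre-image and are flagged `invalid`.
#'
#' @param boxes Box tibble in the standardized frame.
#' @param transform A `standardization_transform`.
#' @return `boxes` translated to the original frame, with a logical
#'   `invalid` column.
#' @export
map_boxes_back <- function(boxes, transform) {
  validate_boxes(boxes)
  out <- dplyr::mutate(
    boxes,
    top = .data$top + transform$crop[["row"]] - transform$pad_before[["row"]],
    left = .data$left + transform$crop[["col"]] - transform$pad_before[["col"]]
  )
  orig <- transform$original
  dplyr::mutate(
    out,
    invalid = .data$top + .data$height <= 0 | .data$top >= orig[["row"]] |
      .data$left + .data$width <= 0 | .data$left >= orig[["col"]]
  )
}
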