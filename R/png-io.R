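#' Write an 8-bit grayscale PNG
#'
#' Lossless single-channel PNG output for reconstructed sagittal images.
#' Values must already be integers in 0..255 — normalization belongs upstream
#' (see [normalize_to_8bit()]); out-of-range input is an error, never silently
#' rescaled.
#'
#' @param image Integer matrix (or 8-bit `csr_image`) with values in 0..255.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_png <- function(image, path) {
  if (inherits(image, "csr_image")) image <- image$pixels
  if (!is.matrix(image)) abort("`image` must be a matrix.")
  if (any(image != trunc(image)) || any(image < 0) || any(image > 255)) {
    abort("PNG input must be integers in 0..255; normalize upstream.")
  }
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG
#'
#' Inverse of [write_png()]: returns the integer 0..255 matrix.
#'
#' @param path PNG file path.
#' @return Integer matrix in 0..255.
#' @export
read_png_gray <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  out <- round_half_up(img * 255)
  storage.mode(out) <- "integer"
  out
}
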