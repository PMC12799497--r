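# Detection boxes are plain tibbles with columns top, left, height, width,
# confidence. Coordinates are 0-based pixel offsets from the image's top-left
# corner; a box occupies the half-open rectangle
# [top, top + height) x [left, left + width), so areas are exact and two
# boxes sharing an edge do not overlap.

#' Construct a tibble of scored detection boxes
#'
#' @param top,left 0-based pixel offsets of the box's top-left corner.
#' @param height,width Box extents in pixels (> 0).
#' @param confidence Detection confidence in `[0, 1]`.
#' @return A tibble with one row per box.
#' @export
scored_boxes <- function(top = numeric(), left = numeric(),
                         height = numeric(), width = numeric(),
                         confidence = numeric()) {
  b <- tibble(
    top = as.numeric(top), left = as.numeric(left),
    height = as.numeric(height), width = as.numeric(width),
    confidence = as.numeric(confidence)
  )
  validate_boxes(b)
  b
}

validate_boxes <- function(b) {
  need <- c("top", "left", "height", "width", "confidence")
  miss <- setdiff(need, names(b))
  if (length(miss)) {
    abort(paste0("Box table lacks columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(b)) {
    if (any(b$height <= 0) || any(b$width <= 0)) {
      abort("Box height and width must be positive.")
    }
    if (any(b$confidence < 0 | b$confidence > 1)) {
      abort("Confidence must lie in [0, 1].")
    }
  }
  invisible(b)
}

#' Intersection over union of two boxes
#'
#' Jaccard overlap of two axis-aligned half-open rectangles; 0 when disjoint,
#' 1 when identical.
#'
#' @param a,b Single-row box tibbles (or lists with `top`, `left`, `height`,
#'   `width`).
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ih <- min(a$top + a$height, b$top + b$height) - max(a$top, b$top)
  iw <- min(a$left + a$width, b$left + b$width) - max(a$left, b$left)
  if (ih <= 0 || iw <= 0) {
    return(0)
  }
  inter <- ih * iw
  inter / (a$height * a$width + b$height * b$width - inter)
}

iou_matrix <- function(b) {
  n <- nrow(b)
  m <- diag(1, n)
  if (n < 2) {
    return(m)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- iou(b[i, ], b[j, ])
    }
  }
  m
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-confidence remaining box and discards every
#' box whose IoU with it exceeds `iou_thresh`. Confidence ties are broken by
#' `(top, left)` lexicographic order so results are identical across
#' platforms. Kept boxes are returned in the order selected
#' (confidence-descending) and are pairwise at or below the threshold.
#'
#' @param boxes A box tibble (see [scored_boxes()]).
#' @param iou_thresh Overlap threshold above which a box is suppressed
#'   (default 0.6).
#' @return The surviving subset of `boxes`.
#' @export
nms <- function(boxes, iou_thresh = 0.6) {
  validate_boxes(boxes)
  if (nrow(boxes) <= 1) {
    return(boxes)
  }
  ord <- order(-boxes$confidence, boxes$top, boxes$left)
  m <- iou_matrix(boxes)
  keep <- integer()
  alive <- ord
  while (length(alive)) {
    k <- alive[1]
    keep <- c(keep, k)
    alive <- alive[m[k, alive] <= iou_thresh]
    alive <- setdiff(alive, k)
  }
  boxes[keep, ]
}
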