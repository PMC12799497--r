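# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as naive loops, independent of the package's
# vectorized implementations.

# A coarse phantom small enough for per-test use (still >= 41 sagittal
# slices so the default slab is interior).
small_spec <- function(seed = 1L, noise_sd = 10, ...) {
  phantom_spec(
    n_vertebrae = 4, spacing = c(2.5, 2, 2),
    margin_x_mm = 35, noise_sd = noise_sd, seed = seed, ...
  )
}

random_volume <- function(nz, ny, nx, seed, lo = -450, hi = 1050) {
  set.seed(seed)
  vox <- array(sample(lo:hi, nz * ny * nx, replace = TRUE), dim = c(nz, ny, nx))
  ct_volume(vox, spacing = c(1, 1, 1))
}

bf_profile <- function(vox) {
  d <- dim(vox)
  out <- numeric(d[3])
  for (x in seq_len(d[3])) {
    s <- 0
    for (z in seq_len(d[1])) {
      for (y in seq_len(d[2])) s <- s + vox[z, y, x]
    }
    out[x] <- s
  }
  out
}

bf_slab <- function(vox, centre, half_width, op = c("sum", "max")) {
  op <- match.arg(op)
  d <- dim(vox)
  lo <- max(1, centre - half_width)
  hi <- min(d[3], centre + half_width)
  out <- matrix(if (op == "sum") 0 else -Inf, d[1], d[2])
  for (z in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      for (x in lo:hi) {
        out[z, y] <- if (op == "sum") {
          out[z, y] + vox[z, y, x]
        } else {
          max(out[z, y], vox[z, y, x])
        }
      }
    }
  }
  out
}

# Greedy NMS oracle with explicit inline geometry (no calls into the package
# beyond data frame columns).
bf_nms <- function(boxes, thresh) {
  df <- as.data.frame(boxes)
  df$.row <- seq_len(nrow(df))
  pair_iou <- function(a, b) {
    ih <- min(a$top + a$height, b$top + b$height) - max(a$top, b$top)
    iw <- min(a$left + a$width, b$left + b$width) - max(a$left, b$left)
    if (ih <= 0 || iw <= 0) {
      return(0)
    }
    (ih * iw) / (a$height * a$width + b$height * b$width - ih * iw)
  }
  kept <- integer()
  remaining <- df[order(-df$confidence, df$top, df$left), ]
  while (nrow(remaining) > 0) {
    best <- remaining[1, ]
    kept <- c(kept, best$.row)
    keep_mask <- logical(nrow(remaining))
    for (k in seq_len(nrow(remaining))) {
      keep_mask[k] <- pair_iou(best, remaining[k, ]) <= thresh
    }
    keep_mask[1] <- FALSE
    remaining <- remaining[keep_mask, ]
  }
  kept
}

random_boxes <- function(n, seed) {
  set.seed(seed)
  scored_boxes(
    top = sample(0:40, n, replace = TRUE),
    left = sample(0:40, n, replace = TRUE),
    height = sample(5:30, n, replace = TRUE),
    width = sample(5:30, n, replace = TRUE),
    # coarse confidences so ties occur and exercise the tie-break
    confidence = sample(seq(0.1, 0.9, by = 0.1), n, replace = TRUE)
  )
}

# Records realising the five-center external-validation confusion layout
# (per-center TP/TN/FP/FN) used across evaluation tests.
five_center_records <- function() {
  counts <- data.frame(
    center = paste("Center", 1:5),
    tp = c(44, 44, 31, 27, 57),
    tn = c(115, 170, 176, 131, 130),
    fp = c(0, 1, 3, 2, 4),
    fn = c(0, 4, 5, 9, 3)
  )
  dplyr::bind_rows(lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ], records_from_counts(tp, tn, fp, fn, center = center))
  }))
}
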