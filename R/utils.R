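# Shared numeric helpers.

#' Round half away from zero
#'
#' Deterministic "half-up" rounding used for the 8-bit conversion so that
#' outputs are bit-identical across platforms (base `round()` rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Truncate to a fixed number of decimals
#'
#' Truncation (round toward zero) used by the table-display helpers: published
#' diagnostic tables in this field often truncate proportions rather than
#' round them (e.g. a lower bound of 0.8999 printed as 0.899).
#'
#' @inheritParams round_half_up
#' @return Numeric vector truncated toward zero.
#' @export
trunc_digits <- function(x, digits = 3) {
  m <- 10^digits
  trunc(x * m) / m
}

#' Format a proportion for display
#'
#' @param x Proportion(s).
#' @param digits Decimals to keep.
#' @param display `"truncate"` (default, matches published tables) or
#'   `"round"` (half-up).
#' @return Numeric vector at display precision (full precision is always kept
#'   by the computing functions; this is presentation only).
#' @export
display_value <- function(x, digits = 3, display = c("truncate", "round")) {
  display <- match.arg(display)
  if (display == "truncate") trunc_digits(x, digits) else round_half_up(x, digits)
}

# Deterministic per-unit sub-seed derivation: a single user seed fans out to
# one sub-seed per case/draw via a Lehmer-style multiplicative step, keeping
# cohort generation reproducible piecewise (case i alone equals case i in a
# batch). Values stay below 2^31 - 1.
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (k in seq_len(2)) s <- (s * 48271 + as.double(index) * 16807) %% m
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
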