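# Oracle detector: a stochastic stand-in for a trained fracture detector,
# driven by phantom ground truth. Its parameters plant known per-grade
# sensitivities and a known case-level false-alarm rate, so the detection
# policy and the evaluation statistics can be validated against values the
# simulation controls exactly.

#' Oracle detector parameters
#'
#' Each true fracture box is emitted with probability `1 - miss_prob` for its
#' grade, with a grade-dependent confidence drawn at or above the case
#' threshold (0.8) — so the planted case-level sensitivity for a grade is
#' exactly `1 - miss_prob`. With probability `fp_case_prob` a fracture-free
#' case receives one high-confidence false box on one of its vertebrae — so
#' the planted specificity is exactly `1 - fp_case_prob`. Independently, a
#' Poisson(`false_box_rate`) stream of low-confidence nuisance boxes
#' (confidence below 0.8, at or above 0.5) exercises the reporting step
#' without flipping case calls.
#'
#' Default miss probabilities fall with grade (harder fractures are easier to
#' detect): minimal 0.25, mild 0.15, moderate 0.05, severe 0.02; the default
#' false-alarm probability 0.014 mirrors the low false-positivity regime of a
#' specificity-emphasised screener.
#'
#' @param miss_prob_by_grade Named numeric vector over
#'   `minimal/mild/moderate/severe`.
#' @param fp_case_prob Probability of a high-confidence false box per case.
#' @param false_box_rate Expected count of low-confidence nuisance boxes per
#'   case.
#' @param conf_base Named vector of lower confidence bounds per grade (all at
#'   or above 0.8); confidences are uniform on `[base, base + 0.08]`.
#' @return An `oracle_params` list.
#' @export
oracle_params <- function(miss_prob_by_grade = c(
                            minimal = 0.25, mild = 0.15,
                            moderate = 0.05, severe = 0.02
                          ),
                          fp_case_prob = 0.014,
                          false_box_rate = 0.2,
                          conf_base = c(
                            minimal = 0.80, mild = 0.84,
                            moderate = 0.88, severe = 0.91
                          )) {
  if (any(miss_prob_by_grade < 0 | miss_prob_by_grade > 1) ||
    fp_case_prob < 0 || fp_case_prob > 1) {
    abort("Probabilities must lie in [0, 1].")
  }
  structure(
    list(
      miss_prob_by_grade = miss_prob_by_grade,
      fp_case_prob = fp_case_prob,
      false_box_rate = false_box_rate,
      conf_base = conf_base
    ),
    class = "oracle_params"
  )
}

# Nominal per-vertebra boxes in the standardized 512 frame, used when a case
# is simulated at ground-truth level without materializing voxels. Vertebrae
# are laid out top-down (superior first) with plausible pixel extents.
nominal_boxes_512 <- function(n_vertebrae) {
  pitch <- floor(480 / max(n_vertebrae, 1))
  h <- max(8, pitch - 6)
  tibble(
    vertebra = seq_len(n_vertebrae),
    top = 16 + (n_vertebrae - seq_len(n_vertebrae)) * pitch,
    left = 220,
    height = h,
    width = 70
  )
}

#' Oracle detector over phantom ground truth
#'
#' Emits scored boxes for a single case according to [oracle_params()]:
#' unmissed fracture boxes at grade-dependent high confidence, an optional
#' case-level false box, and Poisson nuisance boxes. Deterministic under a
#' fixed seed.
#'
#' @param gt A `vf_ground_truth`.
#' @param params An [oracle_params()].
#' @param seed Integer seed for this case.
#' @param boxes Optional per-vertebra geometry (tibble with `vertebra`,
#'   `top`, `left`, `height`, `width`), e.g. from [gt_boxes_csr()] +
#'   [map_boxes_forward()]; defaults to a nominal standardized-frame layout.
#' @return A box tibble with a `vertebra` column.
#' @export
oracle_detector <- function(gt, params = oracle_params(), seed = 1L,
                            boxes = NULL) {
  v <- gt$vertebrae
  geom <- if (is.null(boxes)) {
    nominal_boxes_512(nrow(v))
  } else {
    dplyr::select(boxes, "vertebra", "top", "left", "height", "width")
  }
  with_seed(seed, {
    frac <- v[v$kind %in% FRACTURE_KINDS, ]
    out <- list()
    if (nrow(frac)) {
      miss_p <- params$miss_prob_by_grade[frac$grade]
      hit <- runif(nrow(frac)) >= miss_p
      if (any(hit)) {
        g <- frac$grade[hit]
        conf <- params$conf_base[g] + runif(sum(hit), 0, 0.08)
        b <- dplyr::inner_join(
          tibble(vertebra = frac$index[hit], confidence = pmin(conf, 0.999)),
          geom,
          by = "vertebra"
        )
        out[[length(out) + 1L]] <- b
      }
    }
    clean <- setdiff(v$index, v$index[v$kind %in% FRACTURE_KINDS])
    if (!gt$case_label && length(clean) && runif(1) < params$fp_case_prob) {
      idx <- clean[sample.int(length(clean), 1L)]
      out[[length(out) + 1L]] <- dplyr::inner_join(
        tibble(vertebra = idx, confidence = runif(1, 0.85, 0.95)),
        geom,
        by = "vertebra"
      )
    }
    n_noise <- rpois(1, params$false_box_rate)
    if (n_noise > 0 && length(clean)) {
      idx <- clean[sample.int(length(clean), min(n_noise, length(clean)))]
      out[[length(out) + 1L]] <- dplyr::inner_join(
        tibble(vertebra = idx, confidence = runif(length(idx), 0.5, 0.78)),
        geom,
        by = "vertebra"
      )
    }
    if (!length(out)) {
      return(dplyr::mutate(geom[0, ], confidence = numeric(0)))
    }
    res <- dplyr::bind_rows(out)
    dplyr::select(
      res, "top", "left", "height", "width", "confidence", "vertebra"
    )
  })
}
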