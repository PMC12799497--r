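# Simulated external-validation cohorts: seeded case mixes with a requested
# fracture prevalence, worst-grade distribution, single-fracture share and
# mimic rates, with pseudo-centers and pseudo-manufacturers assigned
# round-robin for subgroup reporting. Default parameters emulate a
# multi-center opportunistic-screening validation set of 956 cases (224
# fracture-positive across five centers, roughly half of them single-VF,
# with OAw and SV mimics common among the negatives).

GRADE_BANDS <- list(
  minimal = c(0.08, 0.19),
  mild = c(0.20, 0.245),
  moderate = c(0.25, 0.40),
  severe = c(0.41, 0.55)
)

sample_height_loss <- function(grade) {
  b <- GRADE_BANDS[[grade]]
  runif(1, b[1], b[2])
}

case_deformities <- function(label_positive, worst_grade, vf_count,
                             oaw, sv, n_vertebrae) {
  defs <- list()
  used <- integer()
  if (label_positive) {
    grades <- vf_grades()[-1]
    worst_i <- match(worst_grade, grades)
    extra <- if (vf_count > 1) {
      sample(grades[seq_len(worst_i)], vf_count - 1, replace = TRUE)
    } else {
      character()
    }
    g_all <- c(worst_grade, extra)
    idx <- sample.int(n_vertebrae, vf_count)
    used <- idx
    for (k in seq_len(vf_count)) {
      defs[[length(defs) + 1L]] <- deformity_spec(
        idx[k], sample(FRACTURE_KINDS, 1), sample_height_loss(g_all[k])
      )
    }
  }
  if (oaw) {
    free <- setdiff(seq_len(n_vertebrae - 1L), c(used, used - 1L))
    if (length(free)) {
      i0 <- free[sample.int(length(free), 1L)]
      used <- c(used, i0, i0 + 1L)
      defs[[length(defs) + 1L]] <- deformity_spec(
        i0, "oa_wedge_pair", runif(1, 0.08, 0.18)
      )
    }
  }
  if (sv) {
    free <- setdiff(seq_len(n_vertebrae), used)
    if (length(free)) {
      defs[[length(defs) + 1L]] <- deformity_spec(
        free[sample.int(length(free), 1L)], "short_vertebra", runif(1, 0.10, 0.25)
      )
    }
  }
  if (length(defs)) dplyr::bind_rows(defs) else NULL
}

#' Generate a simulated validation cohort
#'
#' Each case receives a fracture status (exact counts under `stratified`,
#' else Bernoulli), a worst grade drawn from `grade_mix`, a fracture count
#' (1 with probability `single_vf_share`, otherwise 2-3), mimic flags among
#' the fracture-free cases, a pseudo-center and pseudo-manufacturer
#' (round-robin), and its own derived seed. All randomness flows from `seed`
#' through per-case sub-seeds, so case `i` is reproducible in isolation.
#'
#' @param n_cases Number of cases (default 956).
#' @param prevalence Fracture-positive case fraction (default 224/956).
#' @param grade_mix Named probabilities over `minimal/mild/moderate/severe`
#'   for the worst grade of a positive case.
#' @param mimic_rates Named rates `c(oaw = , sv = )` among fracture-free
#'   cases (defaults 137/732 and 190/732).
#' @param single_vf_share Probability that a positive case has exactly one
#'   fracture (default 0.482).
#' @param n_centers Number of pseudo-centers (default 5).
#' @param seed Cohort seed.
#' @param stratified Exact positive count (default `TRUE`) instead of
#'   Bernoulli sampling.
#' @param materialize `"none"` (ground truth only, default) or `"volume"`
#'   (build every voxel phantom — slow, for small cohorts).
#' @param spec Base [phantom_spec()] shared by all cases (each case gets its
#'   own seed).
#' @return A `vf_cohort`: list of cases, each with `case_id`, `center`,
#'   `manufacturer`, `seed`, `ground_truth`, and optionally `volume`.
#' @export
make_cohort <- function(n_cases = 956, prevalence = 224 / 956,
                        grade_mix = c(
                          minimal = 0.25, mild = 0.20,
                          moderate = 0.35, severe = 0.20
                        ),
                        mimic_rates = c(oaw = 137 / 732, sv = 190 / 732),
                        single_vf_share = 0.482, n_centers = 5,
                        seed = 1L, stratified = TRUE,
                        materialize = c("none", "volume"),
                        spec = phantom_spec()) {
  materialize <- match.arg(materialize)
  if (prevalence < 0 || prevalence > 1) abort("prevalence must lie in [0, 1].")
  if (abs(sum(grade_mix) - 1) > 1e-8) abort("grade_mix must sum to 1.")
  grades <- names(grade_mix)

  labels <- with_seed(derive_seed(seed, 0L), {
    if (stratified) {
      pos <- sample.int(n_cases, round(n_cases * prevalence))
      seq_len(n_cases) %in% pos
    } else {
      runif(n_cases) < prevalence
    }
  })

  manufacturers <- c("SIEMENS", "GE", "UIH", "PHILIPS", "TOSHIBA")
  cases <- purrr::map(seq_len(n_cases), function(i) {
    case_seed <- derive_seed(seed, i)
    with_seed(case_seed, {
      positive <- labels[i]
      worst <- if (positive) sample(grades, 1, prob = grade_mix) else "none"
      vf_count <- if (positive) {
        if (runif(1) < single_vf_share) 1L else sample(2:3, 1)
      } else {
        0L
      }
      oaw <- !positive && runif(1) < mimic_rates[["oaw"]]
      sv <- !positive && runif(1) < mimic_rates[["sv"]]
      defs <- case_deformities(
        positive, worst, vf_count, oaw, sv, spec$n_vertebrae
      )
      case_spec <- spec
      case_spec$seed <- derive_seed(case_seed, 1L)
      gt <- make_ground_truth(case_spec, defs)
      out <- list(
        case_id = sprintf("case-%04d", i),
        center = sprintf("Center %d", 1L + (i - 1L) %% n_centers),
        manufacturer = manufacturers[1L + (i - 1L) %% length(manufacturers)],
        seed = case_seed,
        ground_truth = gt
      )
      if (materialize == "volume") {
        out$volume <- make_spine_volume(case_spec, defs)$volume
      }
      out
    })
  })
  structure(
    list(cases = cases, seed = seed, spec = spec),
    class = "vf_cohort"
  )
}

#' @export
print.vf_cohort <- function(x, ...) {
  labs <- vapply(x$cases, function(cs) cs$ground_truth$case_label, TRUE)
  cat(sprintf(
    "<vf_cohort> %d cases (%d VF-positive), seed %d\n",
    length(x$cases), sum(labs), x$seed
  ))
  invisible(x)
}

worst_grade_of <- function(gt) {
  frac <- gt$vertebrae[gt$vertebrae$kind %in% FRACTURE_KINDS, ]
  if (!nrow(frac)) {
    return("none")
  }
  vf_grades()[max(match(frac$grade, vf_grades()))]
}

#' Run the oracle detector and decision policy over a cohort
#'
#' The ground-truth-level pipeline: for every case, score boxes with the
#' [oracle_detector()] (per-case derived seed), apply [two_step_decision()],
#' and assemble the resulting case-level records for the evaluation module.
#'
#' @param cohort A `vf_cohort`.
#' @param policy A [detection_policy()].
#' @param params An [oracle_params()].
#' @return A `case_records` tibble with one row per case.
#' @export
cohort_records <- function(cohort, policy = detection_policy(),
                           params = oracle_params()) {
  rows <- purrr::map(cohort$cases, function(cs) {
    gt <- cs$ground_truth
    boxes <- oracle_detector(gt, params, seed = derive_seed(cs$seed, 2L))
    res <- two_step_decision(boxes, policy)
    frac <- gt$vertebrae[gt$vertebrae$kind %in% FRACTURE_KINDS, ]
    tibble(
      case_id = cs$case_id,
      predicted_positive = res$case_positive,
      center = cs$center,
      manufacturer = cs$manufacturer,
      vf_count = nrow(frac),
      worst_grade = worst_grade_of(gt),
      oaw = any(gt$vertebrae$kind == "oa_wedge"),
      sv = any(gt$vertebrae$kind == "short_vertebra")
    )
  })
  rec <- dplyr::bind_rows(rows)
  case_records(
    case_id = rec$case_id, predicted_positive = rec$predicted_positive,
    vf_count = rec$vf_count, worst_grade = rec$worst_grade,
    center = rec$center, manufacturer = rec$manufacturer,
    oaw = rec$oaw, sv = rec$sv
  )
}

#' Planted case-level detection probabilities
#'
#' The probability that the oracle flags each case, computed exactly from
#' the oracle parameters: a positive case is detected unless every one of
#' its fractures is missed; a negative case is flagged with the false-alarm
#' probability. These are the reference values that pipeline-measured
#' sensitivity and specificity should recover.
#'
#' @param cohort A `vf_cohort`.
#' @param params An [oracle_params()].
#' @return Tibble with `case_id`, `label_positive`, `p_flag`.
#' @export
planted_case_probabilities <- function(cohort, params = oracle_params()) {
  dplyr::bind_rows(purrr::map(cohort$cases, function(cs) {
    gt <- cs$ground_truth
    frac <- gt$vertebrae[gt$vertebrae$kind %in% FRACTURE_KINDS, ]
    p <- if (nrow(frac)) {
      1 - prod(params$miss_prob_by_grade[frac$grade])
    } else {
      params$fp_case_prob
    }
    tibble(case_id = cs$case_id, label_positive = nrow(frac) > 0, p_flag = p)
  }))
}
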