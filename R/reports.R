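# Report generators reproducing the standard multi-center validation tables:
# per-subgroup diagnostic performance, the single-fracture stratum, the
# fracture-mimic false-positive breakdown, and the case-level error rates.
# All values are computed and returned at full precision; display_metrics()
# applies table-style truncation/rounding for presentation only.

group_metrics_row <- function(rec, level) {
  ct <- confusion(rec)
  m <- metrics(ct)
  sens_ci <- if (ct$tp + ct$fn > 0) {
    wilson_cc_interval(ct$tp, ct$tp + ct$fn, level)
  } else {
    tibble(lower = NA_real_, upper = NA_real_)
  }
  spec_ci <- if (ct$tn + ct$fp > 0) {
    wilson_cc_interval(ct$tn, ct$tn + ct$fp, level)
  } else {
    tibble(lower = NA_real_, upper = NA_real_)
  }
  tibble(
    n = ct$n, tp = ct$tp, tn = ct$tn, fp = ct$fp, fn = ct$fn,
    sensitivity = m$sensitivity,
    sens_lower = sens_ci$lower, sens_upper = sens_ci$upper,
    specificity = m$specificity,
    spec_lower = spec_ci$lower, spec_upper = spec_ci$upper,
    accuracy = m$accuracy
  )
}

#' Per-subgroup diagnostic performance table
#'
#' One row per level of the grouping attribute plus a `"Total"` row, each
#' with confusion counts, sensitivity and specificity with
#' continuity-corrected Wilson intervals, and accuracy. The total row equals
#' the confusion over all records, and every count column sums across groups
#' to the total (partition consistency).
#'
#' @param records A `case_records` tibble.
#' @param by `"center"` or `"manufacturer"`.
#' @param level Confidence level for the intervals (default 0.95).
#' @return A tibble, one row per group plus the total row.
#' @export
subgroup_report <- function(records, by = c("center", "manufacturer"),
                            level = 0.95) {
  by <- match.arg(by)
  validate_case_records(records)
  groups <- sort(unique(records[[by]]))
  rows <- purrr::map(groups, function(g) {
    dplyr::bind_cols(
      tibble(group = g),
      group_metrics_row(records[records[[by]] == g, ], level)
    )
  })
  dplyr::bind_rows(
    rows,
    dplyr::bind_cols(tibble(group = "Total"), group_metrics_row(records, level))
  )
}

#' Single-fracture stratum performance
#'
#' Restricts to cases with exactly one true fracture — the hardest stratum
#' for a case-level screener — and tabulates, per center and overall, the
#' stratum size (with its share of all fracture-positive cases), how many
#' single fractures are of minimal or mild grade, and the detection
#' sensitivity.
#'
#' @param records A `case_records` tibble.
#' @return A tibble with one row per center plus a total row; empty (0 rows)
#'   when there are no single-fracture cases.
#' @export
single_vf_report <- function(records) {
  validate_case_records(records)
  single <- dplyr::filter(records, .data$vf_count == 1L)
  if (nrow(single) == 0) {
    return(tibble(
      group = character(), single_vf = integer(), pct_of_positives = numeric(),
      minimal = integer(), pct_minimal = numeric(),
      mild = integer(), pct_mild = numeric(),
      fn = integer(), tp = integer(), sensitivity = numeric()
    ))
  }
  pos <- dplyr::filter(records, .data$label_positive)
  one_row <- function(s, p, label) {
    tibble(
      group = label,
      single_vf = nrow(s),
      pct_of_positives = if (nrow(p)) 100 * nrow(s) / nrow(p) else NA_real_,
      minimal = sum(s$worst_grade == "minimal"),
      pct_minimal = 100 * sum(s$worst_grade == "minimal") / nrow(s),
      mild = sum(s$worst_grade == "mild"),
      pct_mild = 100 * sum(s$worst_grade == "mild") / nrow(s),
      fn = sum(!s$predicted_positive),
      tp = sum(s$predicted_positive),
      sensitivity = sum(s$predicted_positive) / nrow(s)
    )
  }
  centers <- sort(unique(single$center))
  dplyr::bind_rows(
    purrr::map(centers, function(g) {
      one_row(
        single[single$center == g, ], pos[pos$center == g, ], g
      )
    }),
    list(one_row(single, pos, "Total"))
  )
}

#' False-positive rates on fracture mimics
#'
#' Osteoarthritic wedging (OAw) and acquired short vertebrae (SV) deform the
#' vertebral silhouette without being fractures; a screener is judged on not
#' flagging them. Among fracture-free cases carrying each mimic, the table
#' gives the fraction flagged positive (FP rate, %) and its complement as
#' accuracy.
#'
#' @param records A `case_records` tibble with `oaw`/`sv` flags.
#' @return A tibble with one row per mimic present in the data.
#' @export
mimic_fp_report <- function(records) {
  validate_case_records(records)
  one <- function(flag, label) {
    sub <- dplyr::filter(records, !.data$label_positive & .data[[flag]])
    if (nrow(sub) == 0) {
      return(NULL)
    }
    fp <- sum(sub$predicted_positive)
    tibble(
      mimic = label, cases = nrow(sub), fp = fp,
      fp_rate_pct = 100 * fp / nrow(sub),
      accuracy = 1 - fp / nrow(sub)
    )
  }
  dplyr::bind_rows(one("oaw", "OAw"), one("sv", "SV"))
}

#' Case-level error breakdown
#'
#' Rates behind a validation narrative: the case-level false-negative rate
#' `FN / (TP + FN)` and false-positive rate `FP / (TN + FP)` (both %), the
#' percentage of fracture cases detected once misses are restricted to
#' moderate-or-worse grades (`100 * (1 - FN_moderate_plus / (TP + FN))`), and
#' the share of missed cases whose worst grade is only minimal or mild.
#'
#' @param records A `case_records` tibble with grades populated.
#' @return One-row tibble: `fn_rate_pct`, `fp_rate_pct`,
#'   `moderate_plus_detected_pct`, `minimal_mild_share_of_fn`.
#' @export
error_breakdown <- function(records) {
  validate_case_records(records)
  ct <- confusion(records)
  fn_cases <- dplyr::filter(records, .data$label_positive & !.data$predicted_positive)
  fn_modplus <- sum(fn_cases$worst_grade %in% c("moderate", "severe"))
  tibble(
    fn_rate_pct = if (ct$tp + ct$fn > 0) 100 * ct$fn / (ct$tp + ct$fn) else NA_real_,
    fp_rate_pct = if (ct$tn + ct$fp > 0) 100 * ct$fp / (ct$tn + ct$fp) else NA_real_,
    moderate_plus_detected_pct = if (ct$tp + ct$fn > 0) {
      100 * (1 - fn_modplus / (ct$tp + ct$fn))
    } else {
      NA_real_
    },
    minimal_mild_share_of_fn = if (nrow(fn_cases) > 0) {
      sum(fn_cases$worst_grade %in% c("minimal", "mild")) / nrow(fn_cases)
    } else {
      NA_real_
    }
  )
}

#' Apply table display precision to a report
#'
#' Published diagnostic tables print proportions at 3 decimals, typically by
#' truncation (a lower bound of 0.8999 appears as 0.899). Full precision is
#' always retained by the computing functions; this helper formats a copy for
#' presentation.
#'
#' @param report A report tibble.
#' @param digits Decimals to keep (default 3).
#' @param display `"truncate"` (default) or `"round"`.
#' @return The report with proportion columns at display precision.
#' @export
display_metrics <- function(report, digits = 3, display = c("truncate", "round")) {
  display <- match.arg(display)
  prop_cols <- intersect(
    names(report),
    c(
      "sensitivity", "sens_lower", "sens_upper", "specificity",
      "spec_lower", "spec_upper", "accuracy", "point", "lower", "upper"
    )
  )
  dplyr::mutate(report, dplyr::across(
    dplyr::all_of(prop_cols),
    ~ display_value(.x, digits = digits, display = display)
  ))
}

#' Plot subgroup sensitivity and specificity with intervals
#'
#' Point-range plot of per-group sensitivity and specificity from
#' [subgroup_report()], with their continuity-corrected Wilson intervals.
#'
#' @param report Output of [subgroup_report()].
#' @return A ggplot object.
#' @export
plot_subgroup_performance <- function(report) {
  long <- dplyr::bind_rows(
    dplyr::transmute(report,
      group = .data$group, metric = "sensitivity",
      point = .data$sensitivity, lower = .data$sens_lower, upper = .data$sens_upper
    ),
    dplyr::transmute(report,
      group = .data$group, metric = "specificity",
      point = .data$specificity, lower = .data$spec_lower, upper = .data$spec_upper
    )
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$group, y = .data$point, colour = .data$metric)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "proportion (95% CI)", colour = NULL) +
    ggplot2::theme_minimal()
}
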