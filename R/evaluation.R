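#' Vertebral-fracture grade vocabulary
#'
#' Case-level severity labels ordered by vertebral height loss. `"minimal"`
#' covers fractures below 20 % height loss (including endplate/cortex
#' fractures), `"mild"` 20-25 %, `"moderate"` 25-40 %, `"severe"` above 40 %.
#'
#' @return Ordered character vector of grade labels.
#' @export
vf_grades <- function() c("none", "minimal", "mild", "moderate", "severe")

#' Assemble case-level screening records
#'
#' One row per CT case: the screening call, the reference label, and the
#' subgroup attributes used by the report generators. The reference label is
#' tied to the fracture count (`label_positive` iff `vf_count >= 1`) and the
#' worst grade must be `"none"` exactly for fracture-free cases; violations
#' are errors, not warnings.
#'
#' @param case_id Case identifiers.
#' @param predicted_positive Logical screening calls.
#' @param vf_count True fracture count per case.
#' @param worst_grade Worst fracture grade per case (see [vf_grades()]).
#' @param center,manufacturer Subgroup attributes.
#' @param oaw,sv Logical mimic flags (osteoarthritic wedging, acquired short
#'   vertebrae).
#' @param fn_vertebra_count Optional vertebra-level miss counts.
#' @return A `case_records` tibble.
#' @export
case_records <- function(case_id, predicted_positive, vf_count,
                         worst_grade = NULL, center = "all",
                         manufacturer = "unknown", oaw = FALSE, sv = FALSE,
                         fn_vertebra_count = NA_integer_) {
  n <- length(case_id)
  worst_grade <- worst_grade %||% ifelse(vf_count >= 1, "moderate", "none")
  rec <- tibble(
    case_id = as.character(case_id),
    predicted_positive = as.logical(predicted_positive),
    label_positive = vf_count >= 1,
    center = rep_len(as.character(center), n),
    manufacturer = rep_len(as.character(manufacturer), n),
    vf_count = as.integer(vf_count),
    worst_grade = rep_len(as.character(worst_grade), n),
    oaw = rep_len(as.logical(oaw), n),
    sv = rep_len(as.logical(sv), n),
    fn_vertebra_count = rep_len(as.integer(fn_vertebra_count), n)
  )
  validate_case_records(rec)
  rec
}

validate_case_records <- function(rec) {
  need <- c("case_id", "predicted_positive", "label_positive", "vf_count", "worst_grade")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    abort(paste0("Case records lack columns: ", paste(miss, collapse = ", ")))
  }
  if (!all(rec$worst_grade %in% vf_grades())) {
    abort("Unknown worst_grade label.")
  }
  if (any(rec$label_positive != (rec$vf_count >= 1))) {
    abort("label_positive must equal vf_count >= 1.")
  }
  if (any((rec$worst_grade == "none") != (rec$vf_count == 0))) {
    abort("worst_grade 'none' must coincide with vf_count 0.")
  }
  invisible(rec)
}

#' Expand printed confusion counts into case records
#'
#' Convenience for reproducing published case-by-case tables: builds a
#' records tibble realising exactly the given TP/TN/FP/FN counts. Positive
#' cases default to one moderate fracture; pass `fn_grades` / `tp_grades` to
#' control the grade mix of missed and detected cases.
#'
#' @param tp,tn,fp,fn Non-negative case counts.
#' @param center,manufacturer Subgroup attributes for all generated rows.
#' @param tp_grades,fn_grades Optional grade vectors recycled over the TP /
#'   FN rows.
#' @return A `case_records` tibble with `tp + tn + fp + fn` rows.
#' @export
records_from_counts <- function(tp, tn, fp, fn, center = "all",
                                manufacturer = "unknown",
                                tp_grades = "moderate", fn_grades = "moderate") {
  n <- tp + tn + fp + fn
  pred <- c(rep(TRUE, tp), rep(FALSE, tn), rep(TRUE, fp), rep(FALSE, fn))
  vfc <- c(rep(1L, tp), rep(0L, tn), rep(0L, fp), rep(1L, fn))
  grade <- c(
    rep_len(tp_grades, tp), rep("none", tn), rep("none", fp),
    rep_len(fn_grades, fn)
  )
  case_records(
    case_id = sprintf("%s-%04d", center, seq_len(n)),
    predicted_positive = pred, vf_count = vfc, worst_grade = grade,
    center = center, manufacturer = manufacturer
  )
}

#' Case-level confusion table
#'
#' @param records A `case_records` tibble.
#' @return A `confusion_table`: list with `tp`, `tn`, `fp`, `fn`, `n`.
#' @export
confusion <- function(records) {
  validate_case_records(records)
  if (nrow(records) == 0) abort("No case records.")
  p <- records$predicted_positive
  l <- records$label_positive
  structure(
    list(
      tp = sum(p & l), tn = sum(!p & !l),
      fp = sum(p & !l), fn = sum(!p & l),
      n = nrow(records)
    ),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf(
    "<confusion_table> n = %d: TP %d, TN %d, FP %d, FN %d\n",
    x$n, x$tp, x$tn, x$fp, x$fn
  ))
  invisible(x)
}

#' @export
tidy.confusion_table <- function(x, ...) {
  tibble(
    cell = c("tp", "tn", "fp", "fn"),
    count = c(x$tp, x$tn, x$fp, x$fn)
  )
}

#' @export
glance.confusion_table <- function(x, ...) {
  dplyr::bind_cols(tibble(n = x$n), metrics(x))
}

#' Diagnostic metrics from a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/n`, at full precision. A metric whose denominator is empty is
#' `NA` (not available), never silently 0 or 1.
#'
#' @param t A `confusion_table` (or list with `tp`, `tn`, `fp`, `fn`).
#' @return One-row tibble with `sensitivity`, `specificity`, `accuracy`.
#' @export
metrics <- function(t) {
  safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(
    sensitivity = safe_ratio(t$tp, t$tp + t$fn),
    specificity = safe_ratio(t$tn, t$tn + t$fp),
    accuracy = safe_ratio(t$tp + t$tn, t$tp + t$tn + t$fp + t$fn)
  )
}

#' Continuity-corrected Wilson score interval for a proportion
#'
#' The score interval of Wilson (1927) with Newcombe's continuity correction
#' ("efficient-score method", Newcombe 1998): with `p = x/n`, `q = 1 - p` and
#' `z` the two-sided normal quantile,
#' \deqn{L = \frac{2np + z^2 - 1 - z\sqrt{z^2 - 2 - 1/n + 4p(nq + 1)}}{2(n + z^2)}}
#' \deqn{U = \frac{2np + z^2 + 1 + z\sqrt{z^2 + 2 - 1/n + 4p(nq - 1)}}{2(n + z^2)}}
#' clamped to `[0, 1]`, with `L = 0` when `x = 0` and `U = 1` when `x = n`.
#' This is the interval behind `stats::prop.test(correct = TRUE)` and the one
#' printed in diagnostic-performance tables.
#'
#' @param x Number of successes (`0 <= x <= n`).
#' @param n Number of trials (`>= 1`).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `x`, `n`, `point`, `lower`, `upper`, `level`,
#'   `method`.
#' @export
wilson_cc_interval <- function(x, n, level = 0.95) {
  if (n < 1) abort("Need n >= 1.")
  if (x < 0 || x > n) abort("Need 0 <= x <= n.")
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  q <- 1 - p
  lower <- if (x == 0) {
    0
  } else {
    max(0, (2 * n * p + z^2 - 1 -
      z * sqrt(max(0, z^2 - 2 - 1 / n + 4 * p * (n * q + 1)))) /
      (2 * (n + z^2)))
  }
  upper <- if (x == n) {
    1
  } else {
    min(1, (2 * n * p + z^2 + 1 +
      z * sqrt(max(0, z^2 + 2 - 1 / n + 4 * p * (n * q - 1)))) /
      (2 * (n + z^2)))
  }
  tibble(
    x = x, n = n, point = p, lower = lower, upper = upper,
    level = level, method = "wilson_cc"
  )
}
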