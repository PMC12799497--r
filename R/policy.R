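#' Two-step detection policy parameters
#'
#' The case decision uses a high confidence bar (a case is flagged only when
#' at least one vertebra is detected with confidence at or above `tau_high`),
#' then — only for flagged cases — a lower bar `tau_low` recovers as many of
#' the case's fractures as possible for reporting. Non-maximum suppression at
#' `nms_iou` is applied independently in both steps. The defaults (0.8, 0.5,
#' 0.6) emphasise specificity.
#'
#' @param tau_high Case-flagging confidence threshold (default 0.8).
#' @param tau_low Reporting confidence threshold (default 0.5).
#' @param nms_iou NMS overlap threshold (default 0.6).
#' @return A `detection_policy` list.
#' @export
detection_policy <- function(tau_high = 0.8, tau_low = 0.5, nms_iou = 0.6) {
  if (!(tau_low >= 0 && tau_low <= tau_high && tau_high <= 1)) {
    abort("Need 0 <= tau_low <= tau_high <= 1.")
  }
  if (!(nms_iou > 0 && nms_iou < 1)) abort("Need 0 < nms_iou < 1.")
  structure(
    list(tau_high = tau_high, tau_low = tau_low, nms_iou = nms_iou),
    class = "detection_policy"
  )
}

#' Apply the two-step confidence policy to raw detections
#'
#' Step 1: NMS on the boxes with confidence at or above `tau_high`; the case
#' is positive iff any survive. Step 2: for a positive case, the reported box
#' set is NMS re-run on the full set at or above `tau_low`; a negative case
#' reports no boxes.
#'
#' @param raw_boxes Box tibble from a detector (standardized frame or mapped
#'   back — the policy is frame-agnostic).
#' @param policy A [detection_policy()].
#' @return A `case_detection_result`: list with `case_positive`, `boxes`
#'   (tibble), and `policy`.
#' @export
two_step_decision <- function(raw_boxes, policy = detection_policy()) {
  validate_boxes(raw_boxes)
  high <- nms(
    dplyr::filter(raw_boxes, .data$confidence >= policy$tau_high),
    policy$nms_iou
  )
  positive <- nrow(high) > 0
  boxes <- if (positive) {
    nms(
      dplyr::filter(raw_boxes, .data$confidence >= policy$tau_low),
      policy$nms_iou
    )
  } else {
    raw_boxes[0, ]
  }
  structure(
    list(case_positive = positive, boxes = boxes, policy = policy),
    class = "case_detection_result"
  )
}

#' @export
print.case_detection_result <- function(x, ...) {
  cat(sprintf(
    "<case_detection_result> %s, %d reported box(es) [tau_high %.2f, tau_low %.2f, NMS IoU %.2f]\n",
    if (x$case_positive) "VF POSITIVE" else "negative",
    nrow(x$boxes), x$policy$tau_high, x$policy$tau_low, x$policy$nms_iou
  ))
  invisible(x)
}

#' Run a detector backend on a standardized image
#'
#' The trained detection network is out of scope here; detection is a
#' pluggable backend behind a fixed contract: raw scored boxes in the
#' standardized frame.
#'
#' @param image Standardized image matrix (may be ignored by non-image
#'   backends).
#' @param backend `"oracle"` (phantom ground truth plus stochastic scoring —
#'   see [oracle_detector()]), `"file"` (boxes from a CSV sidecar), or a
#'   function `(image, ...) -> box tibble`.
#' @param ... Backend arguments. For `"oracle"`: `ground_truth`, optional
#'   `params`, `seed`. For `"file"`: `boxes_file` (CSV with columns
#'   `image_id, top, left, height, width, confidence`) and `image_id`.
#' @return A box tibble.
#' @export
run_detector <- function(image, backend, ...) {
  args <- list(...)
  if (is.function(backend)) {
    return(validate_boxes(backend(image, ...)))
  }
  if (identical(backend, "file")) {
    tab <- as_tibble(read.csv(args$boxes_file, stringsAsFactors = FALSE))
    tab <- dplyr::filter(tab, .data$image_id == args$image_id)
    return(validate_boxes(dplyr::select(
      tab, "top", "left", "height", "width", "confidence"
    )))
  }
  if (identical(backend, "oracle")) {
    return(oracle_detector(
      args$ground_truth,
      params = args$params %||% oracle_params(),
      seed = args$seed %||% 1L
    ))
  }
  abort(sprintf("Unknown detector backend: %s", format(backend)))
}
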