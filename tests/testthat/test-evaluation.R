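test_that("confusion tables count cases exactly and respect symmetry", {
  rec <- records_from_counts(203, 722, 10, 21)
  ct <- confusion(rec)
  expect_equal(c(ct$tp, ct$tn, ct$fp, ct$fn), c(203, 722, 10, 21))
  expect_equal(ct$n, 956)

  perfect <- records_from_counts(5, 7, 0, 0)
  ctp <- confusion(perfect)
  expect_equal(ctp$fp + ctp$fn, 0)

  # flipping labels swaps TP<->FP and TN<->FN
  flipped <- case_records(
    case_id = rec$case_id,
    predicted_positive = rec$predicted_positive,
    vf_count = ifelse(rec$vf_count >= 1, 0L, 1L),
    worst_grade = ifelse(rec$vf_count >= 1, "none", "moderate")
  )
  ctf <- confusion(flipped)
  expect_equal(c(ctf$tp, ctf$fp), c(ct$fp, ct$tp))
  expect_equal(c(ctf$tn, ctf$fn), c(ct$fn, ct$tn))

  expect_error(confusion(rec[0, ]), "No case records")
})

test_that("metrics are exact ratios with NA for empty denominators", {
  m <- metrics(list(tp = 203, tn = 722, fp = 10, fn = 21))
  expect_equal(m$sensitivity, 203 / 224)
  expect_equal(m$specificity, 722 / 732)
  expect_equal(m$accuracy, 925 / 956)

  expect_equal(unlist(metrics(list(tp = 1, tn = 1, fp = 0, fn = 0))),
               c(sensitivity = 1, specificity = 1, accuracy = 1))

  m0 <- metrics(list(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(m0$sensitivity))
  expect_equal(m0$specificity, 1)
})

test_that("continuity-corrected Wilson interval agrees with prop.test", {
  for (n in c(44, 108, 224, 732)) {
    for (x in unique(pmin(c(0, 1, 5, 17, 44, 203, n - 1, n), n))) {
      got <- wilson_cc_interval(x, n)
      want <- stats::prop.test(x, n, correct = TRUE)$conf.int
      expect_equal(got$lower, want[1], tolerance = 1e-10,
        label = sprintf("lower x=%d n=%d", x, n)
      )
      expect_equal(got$upper, want[2], tolerance = 1e-10,
        label = sprintf("upper x=%d n=%d", x, n)
      )
      # structural invariants
      expect_lte(got$lower, got$point)
      expect_gte(got$upper, got$point)
      # never narrower than the uncorrected Wilson interval
      plain <- stats::prop.test(x, n, correct = FALSE)$conf.int
      expect_lte(got$lower, plain[1] + 1e-12)
      expect_gte(got$upper, plain[2] - 1e-12)
    }
  }
  expect_error(wilson_cc_interval(1, 0), "n >= 1")
  expect_error(wilson_cc_interval(5, 4), "0 <= x <= n")
})

test_that("continuity-corrected interval achieves nominal coverage", {
  n <- 224
  for (p in c(0.5, 0.9, 0.986)) {
    set.seed(round(1000 * p))
    xs <- rbinom(2000, n, p)
    covered <- vapply(xs, function(x) {
      ci <- wilson_cc_interval(x, n)
      ci$lower <= p && p <= ci$upper
    }, TRUE)
    expect_gte(mean(covered), 0.94)
  }
})

test_that("subgroup report reproduces per-center rows and partitions exactly", {
  rec <- five_center_records()
  rep <- subgroup_report(rec, by = "center")
  total <- rep[rep$group == "Total", ]
  expect_equal(c(total$tp, total$tn, total$fp, total$fn), c(203, 722, 10, 21))
  # partition consistency for every count column
  groups <- rep[rep$group != "Total", ]
  for (col in c("n", "tp", "tn", "fp", "fn")) {
    expect_equal(sum(groups[[col]]), total[[col]])
  }
  # single group equals overall metrics
  rec1 <- records_from_counts(10, 20, 1, 2, center = "only")
  rep1 <- subgroup_report(rec1, by = "center")
  expect_equal(rep1$sensitivity[1], rep1$sensitivity[2])

  # display truncation reproduces table-style values: 44/44 lower prints 0.899
  c1 <- display_metrics(rep[rep$group == "Center 1", ])
  expect_equal(c1$sens_lower, 0.899)
  expect_equal(c1$sensitivity, 1)
  expect_equal(c1$sens_upper, 1)
})

test_that("single-fracture stratum report matches its per-center arithmetic", {
  centers <- paste("Center", 1:5)
  single <- data.frame(
    center = centers,
    n = c(19, 23, 17, 24, 25),
    minimal = c(6, 4, 2, 10, 5),
    mild = c(4, 5, 5, 3, 5),
    fn = c(0, 4, 2, 6, 2)
  )
  pos_totals <- c(44, 48, 36, 36, 60) # TP + FN per center
  rows <- lapply(seq_len(5), function(i) {
    s <- single[i, ]
    grades <- c(
      rep("minimal", s$minimal), rep("mild", s$mild),
      rep("moderate", s$n - s$minimal - s$mild)
    )
    # misses drawn from the minimal/mild end, detections from the rest
    pred <- rep(TRUE, s$n)
    pred[seq_len(s$fn)] <- FALSE
    extra_pos <- pos_totals[i] - s$n # multi-fracture positive cases
    case_records(
      case_id = sprintf("%s-%03d", s$center, seq_len(s$n + extra_pos)),
      predicted_positive = c(pred, rep(TRUE, extra_pos)),
      vf_count = c(rep(1L, s$n), rep(2L, extra_pos)),
      worst_grade = c(grades, rep("moderate", extra_pos)),
      center = s$center
    )
  })
  rec <- dplyr::bind_rows(rows)
  rep <- single_vf_report(rec)
  tot <- rep[rep$group == "Total", ]
  expect_equal(tot$single_vf, 108)
  expect_equal(tot$fn, 14)
  expect_equal(tot$tp, 94)
  expect_equal(tot$sensitivity, 94 / 108)
  expect_equal(round(tot$pct_of_positives, 1), 48.2)
  expect_equal(tot$minimal, 27)
  expect_equal(tot$mild, 22)
  c4 <- rep[rep$group == "Center 4", ]
  expect_equal(c4$sensitivity, 0.75)
  expect_equal(round(c4$pct_minimal, 1), 41.7)

  # no single-fracture cases: empty table, no division anywhere
  multi <- records_from_counts(3, 3, 0, 0)
  multi$vf_count <- ifelse(multi$vf_count >= 1, 2L, 0L)
  expect_equal(nrow(single_vf_report(multi)), 0)

  # all detected: sensitivity 1
  all_hit <- records_from_counts(4, 2, 0, 0)
  expect_equal(single_vf_report(all_hit)$sensitivity, c(1, 1))
})

test_that("mimic false-positive rates count flagged negatives only", {
  neg_oaw <- case_records(
    case_id = sprintf("o%03d", 1:137),
    predicted_positive = c(rep(TRUE, 6), rep(FALSE, 131)),
    vf_count = 0L, worst_grade = "none", oaw = TRUE
  )
  neg_sv <- case_records(
    case_id = sprintf("s%03d", 1:190),
    predicted_positive = c(TRUE, rep(FALSE, 189)),
    vf_count = 0L, worst_grade = "none", sv = TRUE
  )
  rep <- mimic_fp_report(dplyr::bind_rows(neg_oaw, neg_sv))
  oaw <- rep[rep$mimic == "OAw", ]
  expect_equal(oaw$cases, 137)
  expect_equal(oaw$fp, 6)
  expect_equal(round(oaw$fp_rate_pct, 1), 4.4)
  expect_equal(trunc_digits(oaw$accuracy, 3), 0.956)
  sv <- rep[rep$mimic == "SV", ]
  expect_equal(round(sv$fp_rate_pct, 1), 0.5)
  expect_equal(trunc_digits(sv$accuracy, 3), 0.994)

  expect_equal(nrow(mimic_fp_report(records_from_counts(1, 1, 0, 0))), 0)
})

test_that("error breakdown computes the case-level rates at full precision", {
  rec <- records_from_counts(
    203, 722, 10, 21,
    fn_grades = c(rep("minimal", 6), rep("mild", 5), rep("moderate", 10))
  )
  eb <- error_breakdown(rec)
  expect_equal(eb$fn_rate_pct, 100 * 21 / 224)
  expect_equal(eb$fp_rate_pct, 100 * 10 / 732)
  expect_equal(eb$moderate_plus_detected_pct, 100 * (1 - 10 / 224))
  expect_equal(eb$minimal_mild_share_of_fn, 11 / 21)

  none_missed <- records_from_counts(9, 5, 1, 0)
  eb0 <- error_breakdown(none_missed)
  expect_equal(eb0$fn_rate_pct, 0)
  expect_equal(eb0$moderate_plus_detected_pct, 100)
  expect_true(is.na(eb0$minimal_mild_share_of_fn))
})

test_that("display precision separates truncation from rounding", {
  expect_equal(display_value(0.8999895, 3, "truncate"), 0.899)
  expect_equal(display_value(0.8999895, 3, "round"), 0.9)
  expect_equal(display_value(925 / 956, 3, "truncate"), 0.967)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(63.75), 64)
})
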