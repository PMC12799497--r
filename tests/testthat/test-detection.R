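test_that("IoU matches hand-computed overlaps", {
  a <- scored_boxes(0, 0, 10, 10, 0.9)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, scored_boxes(20, 20, 5, 5, 0.5)), 0)
  # 5x5 intersection over 100 + 100 - 25
  expect_equal(iou(a, scored_boxes(5, 5, 10, 10, 0.5)), 25 / 175)
  # touching edges (half-open boxes) do not overlap
  expect_equal(iou(a, scored_boxes(0, 10, 10, 10, 0.5)), 0)
})

test_that("greedy NMS keeps the winner among overlapping boxes", {
  one <- scored_boxes(3, 4, 10, 10, 0.7)
  expect_identical(nms(one, 0.6), one)

  # two 10x10 boxes offset by d have IoU (10-d)/(10+d); d = 30/17 gives 0.7
  a <- scored_boxes(0, 0, 10, 10, 0.9)
  b <- scored_boxes(0, 30 / 17, 10, 10, 0.8)
  both <- dplyr::bind_rows(a, b)
  expect_equal(iou(both[1, ], both[2, ]), 0.7)
  kept <- nms(both, 0.6)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)
})

test_that("NMS equals the brute-force greedy oracle on random instances", {
  for (s in 1:200) {
    n <- sample(0:6, 1)
    b <- random_boxes(n, seed = 1000 + s)
    got <- nms(b, 0.5)
    want_rows <- bf_nms(b, 0.5)
    expect_identical(got, b[want_rows, ], label = paste("seed", 1000 + s))
    # structural properties: subset, confidence-sorted, pairwise below thresh
    expect_true(all(diff(got$confidence) <= 0))
    if (nrow(got) > 1) {
      for (i in seq_len(nrow(got) - 1)) {
        for (j in (i + 1):nrow(got)) {
          expect_lte(iou(got[i, ], got[j, ]), 0.5)
        }
      }
    }
  }
})

test_that("512 standardization crops/pads per the stated rules", {
  # identity on an exact fit
  img <- matrix(7L, 512, 512)
  s <- standardize_512(img)
  expect_identical(s$image, img)
  expect_equal(unname(s$transform$crop), c(0, 0))
  expect_equal(unname(s$transform$pad_before), c(0, 0))

  # 600 x 400: rows center-cropped (offset 44), cols padded 56 | 56
  img2 <- matrix(0L, 600, 400)
  img2[301, 201] <- 99L # marked pixel at 0-based (300, 200)
  s2 <- standardize_512(img2)
  expect_equal(unname(s2$transform$crop), c(44, 0))
  expect_equal(unname(s2$transform$pad_before), c(0, 56))
  expect_equal(unname(s2$transform$pad_after), c(0, 56))
  expect_equal(s2$image[257, 257], 99L) # 0-based (256, 256)

  # 1 x 1 lands at 0-based (255, 255)
  s3 <- standardize_512(matrix(5L, 1, 1))
  expect_equal(s3$image[256, 256], 5L)
  expect_equal(sum(s3$image), 5L)
})

test_that("box coordinates invert exactly through the standardization map", {
  s2 <- standardize_512(matrix(0L, 600, 400))
  b <- scored_boxes(256, 256, 10, 10, 0.9)
  back <- map_boxes_back(b, s2$transform)
  expect_equal(back$top, 300)
  expect_equal(back$left, 200)
  expect_false(back$invalid)

  # identity transform keeps boxes unchanged
  s1 <- standardize_512(matrix(0L, 512, 512))
  b1 <- map_boxes_back(b, s1$transform)
  expect_equal(b1$top, 256)

  # a box entirely in the padded margin has no pre-image
  pad_box <- scored_boxes(0, 10, 8, 8, 0.9)
  expect_true(map_boxes_back(pad_box, s2$transform)$invalid)

  # round trip: forward then back is the identity inside the retained region
  fwd <- map_boxes_forward(scored_boxes(300, 200, 12, 20, 0.8), s2$transform)
  rt <- map_boxes_back(fwd, s2$transform)
  expect_equal(rt$top, 300)
  expect_equal(rt$left, 200)
})

test_that("two-step policy flags on the high bar and reports at the low bar", {
  disjoint <- scored_boxes(
    c(0, 100, 200), c(0, 0, 0), 30, 60, c(0.85, 0.55, 0.45)
  )
  res <- two_step_decision(disjoint)
  expect_true(res$case_positive)
  expect_equal(sort(res$boxes$confidence), c(0.55, 0.85))

  empty <- two_step_decision(disjoint[0, ])
  expect_false(empty$case_positive)
  expect_equal(nrow(empty$boxes), 0)

  # boxes above tau_low but none above tau_high: negative, nothing reported
  low_only <- scored_boxes(c(0, 100), c(0, 0), 30, 60, c(0.79, 0.75))
  res2 <- two_step_decision(low_only)
  expect_false(res2$case_positive)
  expect_equal(nrow(res2$boxes), 0)

  # with tau_high = tau_low the reported set is exactly the step-1 survivors
  p <- detection_policy(tau_high = 0.7, tau_low = 0.7)
  res3 <- two_step_decision(disjoint, p)
  expect_identical(
    res3$boxes,
    nms(dplyr::filter(disjoint, confidence >= 0.7), p$nms_iou)
  )
})

test_that("raising the flagging threshold never converts negatives to positives", {
  for (s in 1:40) {
    b <- random_boxes(sample(1:6, 1), seed = 2000 + s)
    taus <- seq(0.5, 0.95, by = 0.05)
    flags <- vapply(taus, function(th) {
      two_step_decision(b, detection_policy(tau_high = th, tau_low = 0.5))$case_positive
    }, TRUE)
    # monotone non-increasing in tau_high
    expect_true(all(diff(as.integer(flags)) <= 0), label = paste("seed", 2000 + s))
  }
})

test_that("detector backends honour their contracts", {
  d <- withr::local_tempdir()
  csv <- file.path(d, "boxes.csv")
  write.csv(
    data.frame(
      image_id = c("a", "a", "a", "b"),
      top = c(1, 2, 3, 4), left = 5, height = 10, width = 10,
      confidence = c(0.9, 0.8, 0.7, 0.6)
    ),
    csv,
    row.names = FALSE
  )
  got <- run_detector(NULL, "file", boxes_file = csv, image_id = "a")
  expect_equal(nrow(got), 3)
  expect_equal(got$confidence, c(0.9, 0.8, 0.7))

  expect_error(run_detector(NULL, "neural"), "Unknown detector backend")

  gt <- make_ground_truth(small_spec(seed = 9), deformity_spec(2, "fracture_wedge", 0.3))
  b1 <- oracle_detector(gt, seed = 42)
  b2 <- oracle_detector(gt, seed = 42)
  expect_identical(b1, b2)
})
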