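test_that("phantom generation is deterministic under a fixed seed", {
  d1 <- make_spine_volume(small_spec(seed = 12), deformity_spec(3, "fracture_wedge", 0.3))
  d2 <- make_spine_volume(small_spec(seed = 12), deformity_spec(3, "fracture_wedge", 0.3))
  expect_identical(d1$volume$voxels, d2$volume$voxels)
  expect_identical(d1$ground_truth$vertebrae, d2$ground_truth$vertebrae)
  d3 <- make_spine_volume(small_spec(seed = 13), deformity_spec(3, "fracture_wedge", 0.3))
  expect_false(identical(d1$volume$voxels, d3$volume$voxels))
})

test_that("ground truth matches between voxel and geometry-only paths", {
  defs <- dplyr::bind_rows(
    deformity_spec(1, "fracture_biconcave", 0.35),
    deformity_spec(3, "short_vertebra", 0.15)
  )
  full <- make_spine_volume(small_spec(seed = 14), defs)$ground_truth
  light <- make_ground_truth(small_spec(seed = 14), defs)
  expect_identical(full$vertebrae, light$vertebrae)
  expect_identical(full$case_label, light$case_label)
})

test_that("a planted wedge reduces anterior height by the requested fraction", {
  hlf <- 0.30
  sp <- small_spec(seed = 15, noise_sd = 0)
  ph <- make_spine_volume(sp, deformity_spec(2, "fracture_wedge", hlf))
  v <- ph$ground_truth$vertebrae[2, ]
  vox <- ph$volume$voxels
  x <- ph$ground_truth$spine_plane_x
  dz <- sp$spacing[1]
  dy <- sp$spacing[2]
  z_keep <- which((seq_len(dim(vox)[1]) - 1) * dz >= v$z0_mm - dz / 2 &
    (seq_len(dim(vox)[1]) - 1) * dz <= v$z1_mm + dz / 2)
  jj <- which((seq_len(dim(vox)[2]) - 1) * dy >= v$y0_mm &
    (seq_len(dim(vox)[2]) - 1) * dy <= v$y1_mm)
  heights <- vapply(jj, function(j) {
    sum(vox[z_keep, j, x] >= sp$trabecular_hu - 1)
  }, 0)
  ratio <- heights[1] / heights[length(heights)]
  expect_lt(abs(ratio - (1 - hlf)), dz / sp$vertebral_height_mm + 1e-9)
})

test_that("deformity grades follow the height-loss bands", {
  expect_equal(
    grade_from_height_loss(c(0, 0.05, 0.1, 0.19, 0.2, 0.24, 0.25, 0.4, 0.41, 0.6)),
    c(
      "none", "none", "minimal", "minimal", "mild", "mild",
      "moderate", "moderate", "severe", "severe"
    )
  )
  expect_equal(deformity_spec(2, "fracture_crush", 0.5)$grade, "severe")
  # the OA pair expands to two adjacent label-negative rows
  pair <- deformity_spec(3, "oa_wedge_pair", 0.15)
  expect_equal(pair$vertebra_index, c(3L, 4L))
  expect_equal(unique(pair$grade), "none")
  expect_error(deformity_spec(1, "fracture_wedge", 1.2), "\\[0, 1\\)")
})

test_that("case labels come from fractures only, never from mimics", {
  clean <- make_ground_truth(small_spec())
  expect_false(clean$case_label)
  expect_equal(sum(clean$vertebrae$kind != "none"), 0)

  mimics <- make_ground_truth(
    small_spec(),
    dplyr::bind_rows(
      deformity_spec(1, "oa_wedge_pair", 0.15),
      deformity_spec(4, "short_vertebra", 0.2)
    )
  )
  expect_false(mimics$case_label)

  frac <- make_ground_truth(small_spec(), deformity_spec(2, "fracture_crush", 0.3))
  expect_true(frac$case_label)

  expect_error(
    make_ground_truth(small_spec(), dplyr::bind_rows(
      deformity_spec(2, "fracture_wedge", 0.3),
      deformity_spec(2, "fracture_crush", 0.3)
    )),
    "Overlapping"
  )
  expect_error(
    make_ground_truth(small_spec(), deformity_spec(9, "fracture_wedge", 0.3)),
    "exceeds"
  )
})

test_that("oracle emits exactly the ground-truth boxes when noise is off", {
  gt <- make_ground_truth(
    small_spec(seed = 16),
    dplyr::bind_rows(
      deformity_spec(1, "fracture_wedge", 0.3),
      deformity_spec(3, "fracture_crush", 0.45)
    )
  )
  p <- oracle_params(
    miss_prob_by_grade = c(minimal = 0, mild = 0, moderate = 0, severe = 0),
    fp_case_prob = 0, false_box_rate = 0
  )
  b <- oracle_detector(gt, p, seed = 1)
  expect_equal(sort(b$vertebra), c(1, 3))
  expect_true(all(b$confidence >= 0.8))
})

test_that("oracle miss rates realise their planted probabilities", {
  co <- make_cohort(
    n_cases = 500, prevalence = 1,
    grade_mix = c(minimal = 1, mild = 0, moderate = 0, severe = 0),
    single_vf_share = 1, seed = 77, spec = small_spec()
  )
  p <- oracle_params(miss_prob_by_grade = c(
    minimal = 0.5, mild = 0.5, moderate = 0.5, severe = 0.5
  ))
  rec <- cohort_records(co, params = p)
  miss_frac <- mean(!rec$predicted_positive)
  # 95% binomial interval around the planted 0.5 at n = 500
  expect_lt(abs(miss_frac - 0.5), 1.96 * sqrt(0.25 / 500))
})

test_that("cohorts honour prevalence, grade mix and mimic structure", {
  co <- make_cohort(n_cases = 956, seed = 5, spec = small_spec())
  labs <- vapply(co$cases, function(cs) cs$ground_truth$case_label, TRUE)
  expect_equal(sum(labs), 224) # stratified: exact count

  co0 <- make_cohort(n_cases = 40, prevalence = 0, seed = 6, spec = small_spec())
  expect_false(any(vapply(co0$cases, function(cs) cs$ground_truth$case_label, TRUE)))

  co_sev <- make_cohort(
    n_cases = 30, prevalence = 1,
    grade_mix = c(minimal = 0, mild = 0, moderate = 0, severe = 1),
    seed = 7, spec = small_spec()
  )
  rec <- cohort_records(co_sev)
  expect_true(all(rec$worst_grade == "severe"))

  # records are reproducible and centers partition round-robin
  rec2 <- cohort_records(co_sev)
  expect_identical(rec, rec2)
  expect_equal(sort(unique(rec$center)), paste("Center", 1:5))
})

test_that("written fixtures pass eligibility and carry their manifest", {
  ph <- make_spine_volume(small_spec(seed = 18), deformity_spec(2, "fracture_wedge", 0.3))
  d <- withr::local_tempdir()
  write_case_fixture(ph$volume, ph$ground_truth, d)
  vol <- load_series(file.path(d, "dicom"))
  expect_true(check_eligibility(vol$meta)$eligible)
  gt <- read_case_manifest(d)
  expect_true(gt$case_label)
  expect_equal(gt$vertebrae$kind[2], "fracture_wedge")
  expect_equal(nrow(gt$vertebrae), 4)
})

test_that("ground-truth boxes land on the fractured vertebra in the CSR frame", {
  sp <- small_spec(seed = 19, noise_sd = 0)
  ph <- make_spine_volume(sp, deformity_spec(2, "fracture_crush", 0.4))
  slab <- reconstruct_csr(ph$volume)
  boxes <- gt_boxes_csr(ph$ground_truth, slab)
  expect_equal(nrow(boxes), 1)
  expect_equal(boxes$vertebra, 2)
  # the box must lie inside the image and below its vertical midline
  # (vertebra 2 of 4 sits in the inferior half; rows run superior->inferior)
  expect_gte(boxes$top, 0)
  expect_lte(boxes$top + boxes$height, nrow(slab$pixels))
  expect_gt(boxes$top, nrow(slab$pixels) / 2)
})
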