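test_that("window clamp maps HU onto the configured range and is idempotent", {
  vol <- ct_volume(
    array(c(-1000, 2000, 300, -450, 1050, 0), dim = c(1, 2, 3)),
    spacing = c(1, 1, 1)
  )
  w1 <- apply_window(vol)
  expect_equal(
    as.vector(w1$voxels), c(-450, 1050, 300, -450, 1050, 0)
  )
  expect_equal(apply_window(w1)$voxels, w1$voxels)
  # custom window bounds
  w2 <- apply_window(vol, window_settings(width = 400, level = 40))
  expect_equal(range(w2$voxels), c(-160, 240))
})

test_that("sagittal profile equals brute-force plane sums", {
  vol_const <- ct_volume(array(7, dim = c(4, 5, 6)), spacing = c(1, 1, 1))
  expect_equal(sagittal_sum_profile(vol_const), rep(20 * 7, 6))

  vol <- random_volume(6, 5, 4, seed = 11)
  expect_equal(sagittal_sum_profile(vol), bf_profile(vol$voxels))

  # planted high-HU column wins the argmax
  vol$voxels[, , 3] <- vol$voxels[, , 3] + 1e6
  expect_equal(central_index(sagittal_sum_profile(vol)), 3L)
})

test_that("central index takes the first maximum and rejects empty input", {
  expect_equal(central_index(c(1, 5, 3)), 2L)
  expect_equal(central_index(c(2, 2, 2)), 1L)
  expect_error(central_index(numeric()), "empty")
})

test_that("slab projections match independent triple-loop oracles", {
  vol <- random_volume(9, 7, 45, seed = 21)
  slab <- csr_project(vol, 23, 20)
  expect_equal(slab$pixels, bf_slab(vol$voxels, 23, 20, "sum"))
  expect_equal(slab$n_slices, 41L)

  mip <- mip_project(vol, 23, 20)
  expect_equal(mip$pixels, bf_slab(vol$voxels, 23, 20, "max"))

  # border clamping sums only existing slices
  edge <- csr_project(vol, 2, 20)
  expect_equal(edge$pixels, bf_slab(vol$voxels, 2, 20, "sum"))
  expect_equal(edge$n_slices, 22L)

  expect_error(csr_project(vol, 23, -1), "non-negative")
})

test_that("degenerate slabs reduce to the single central slice", {
  vol <- random_volume(5, 6, 45, seed = 31)
  expect_equal(csr_project(vol, 17, 0)$pixels, vol$voxels[, , 17])
  expect_equal(mpr_slice(vol, 17)$pixels, vol$voxels[, , 17])
  # constant volume: CSR pixel is 41 v, MIP pixel is v
  vc <- ct_volume(array(12, dim = c(3, 3, 45)), spacing = c(1, 1, 1))
  expect_true(all(csr_project(vc, 23, 20)$pixels == 41 * 12))
  expect_true(all(mip_project(vc, 23, 20)$pixels == 12))
})

test_that("slab projection is linear in the input volume", {
  vol <- random_volume(6, 6, 45, seed = 41)
  vol2 <- vol
  vol2$voxels <- 2 * vol2$voxels
  expect_equal(csr_project(vol2, 23, 20)$pixels, 2 * csr_project(vol, 23, 20)$pixels)
})

test_that("8-bit conversion is a monotone min-max map with half-up rounding", {
  slab <- csr_project(
    ct_volume(array(0, dim = c(2, 2, 1)), spacing = c(1, 1, 1)), 1, 0
  )
  slab$pixels <- matrix(c(0, 100, 50, 25), 2, 2) # [[0, 50], [100, 25]]
  out <- normalize_to_8bit(slab)
  expect_identical(out$pixels, matrix(c(0L, 255L, 128L, 64L), 2, 2))

  slab$pixels <- matrix(5, 3, 3)
  expect_true(all(normalize_to_8bit(slab)$pixels == 0L))

  slab$pixels <- matrix(rnorm(64), 8, 8)
  out <- normalize_to_8bit(slab)
  expect_equal(min(out$pixels), 0L)
  expect_equal(max(out$pixels), 255L)
  expect_true(all(order(slab$pixels) == order(slab$pixels))) # ordering preserved
  expect_true(all(diff(out$pixels[order(slab$pixels)]) >= 0))
})

test_that("isotropic resampling preserves physical extent and linear ramps", {
  vol <- random_volume(10, 8, 45, seed = 51)
  vol$spacing <- c(2, 1, 1) # dz = 2 dy
  slab <- csr_project(vol, 23, 10)
  iso <- resample_isotropic(slab)
  expect_equal(nrow(iso$pixels), 2 * 10 - 1)
  expect_equal(iso$pixel_spacing[1], iso$pixel_spacing[2])

  # a linear ramp along z stays a linear ramp
  ramp <- slab
  ramp$pixels <- matrix(rep(seq(0, 90, by = 10), 8), 10, 8)
  iso_r <- resample_isotropic(ramp)
  expect_equal(iso_r$pixels[, 1], seq(0, 90, by = 5))

  # already isotropic: identity
  slab$pixel_spacing <- c(1, 1)
  expect_identical(resample_isotropic(slab)$pixels, slab$pixels)
})

test_that("full reconstruction equals the manual composition of its steps", {
  ph <- make_spine_volume(small_spec(seed = 6), deformity_spec(2, "fracture_crush", 0.3))
  auto <- reconstruct_csr(ph$volume)

  wv <- apply_window(ph$volume, window_settings())
  cidx <- central_index(sagittal_sum_profile(wv))
  slab <- csr_project(wv, cidx, 20)
  slab$pixels <- slab$pixels[rev(seq_len(nrow(slab$pixels))), , drop = FALSE]
  manual <- normalize_to_8bit(resample_isotropic(slab))
  expect_identical(auto$pixels, manual$pixels)
  expect_equal(auto$central_index, cidx)
})

test_that("uniform air reconstructs to an all-zero image", {
  vol <- ct_volume(array(-1000, dim = c(4, 5, 45)), spacing = c(1, 1, 1))
  out <- reconstruct_csr(vol)
  expect_true(all(out$pixels == 0L))
})

test_that("shifting the planted spine plane shifts the recovered centre equally", {
  base <- 20L
  for (delta in c(0L, 3L)) {
    ph <- make_spine_volume(
      small_spec(seed = 8, spine_plane_x = base + delta, noise_sd = 0)
    )
    prof <- sagittal_sum_profile(apply_window(ph$volume))
    expect_equal(central_index(prof), base + delta)
  }
})
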