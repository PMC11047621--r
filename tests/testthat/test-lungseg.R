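test_that("segmentation recovers the phantom lung label almost exactly", {
  ps <- generate_phantom(small_spec())
  m <- segment_lungs(ps$tnc)
  expect_s3_class(m, "lung_mask")
  expect_identical(dim(m$mask), dim(ps$tnc$voxels))
  expect_equal(m$component_count, 2L)
  expect_gte(dice(m$mask, ps$truth$lung_label), 0.99)
  # volume agrees with the analytic ellipsoid volume within 2%
  va <- analytic_truth(ps$spec)$lung_volume_cm3
  expect_lt(abs(mask_volume_cm3(m) - va) / va, 0.02)
})

test_that("volumes without lungs raise an empty-segmentation error", {
  solid <- ct_volume(array(40, c(8L, 32L, 32L)), c(2, 2, 2))
  expect_error(segment_lungs(solid), "empty segmentation")
})

test_that("mask volume is voxel count times voxel volume", {
  m <- array(FALSE, c(10L, 10L, 10L))
  m[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  expect_equal(mask_volume_cm3(m, voxel_volume_cm3 = 0.001), 1)
  expect_equal(mask_volume_cm3(array(FALSE, c(2, 2, 2)), 0.001), 0)
})

test_that("segmentation is deterministic and padding-invariant", {
  ps <- generate_phantom(small_spec(noise_sigma_hu = 20))
  m1 <- segment_lungs(ps$tnc)
  m2 <- segment_lungs(ps$tnc)
  expect_identical(m1$mask, m2$mask)

  # prepend/append pure-air slices: mask on original slices unchanged
  d <- dim(ps$tnc$voxels)
  padded <- array(-1000, d + c(4L, 0L, 0L))
  padded[3:(d[1] + 2), , ] <- ps$tnc$voxels
  mp <- segment_lungs(ct_volume(padded, ps$tnc$spacing))
  expect_identical(mp$mask[3:(d[1] + 2), , ], m1$mask)
  expect_false(any(mp$mask[c(1, 2, d[1] + 3, d[1] + 4), , ]))
})

test_that("raising the air threshold never shrinks the candidate set", {
  ps <- generate_phantom(small_spec(noise_sigma_hu = 30))
  v <- ps$tnc$voxels
  thresholds <- c(-600, -400, -320, -200)
  counts <- vapply(thresholds, function(t) sum(v < t), numeric(1))
  expect_true(all(diff(counts) >= 0))
})
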