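test_that("emphysema fraction extremes behave as specified", {
  ps0 <- generate_phantom(small_spec(emphysema_fraction = 0))
  expect_false(any(ps0$tnc$voxels[ps0$truth$lung_label] <= -950))
  expect_equal(ps0$truth$emphysema_pct, 0)

  ps1 <- generate_phantom(small_spec(emphysema_fraction = 1))
  expect_true(all(ps1$tnc$voxels[ps1$truth$lung_label] <= -950))
  expect_equal(ps1$truth$emphysema_pct, 100)
})

test_that("generated emphysema fraction matches the target within a cluster", {
  spec <- phantom_spec(grid_shape = c(40L, 128L, 128L),
                       voxel_spacing = c(0.9, 3.2, 3.2),
                       emphysema_fraction = 0.15, noise_sigma_hu = 0)
  ps <- generate_phantom(spec)
  # direct count in the generated volume is the oracle
  n_lung <- sum(ps$truth$lung_label)
  n_low <- sum(ps$tnc$voxels[ps$truth$lung_label] <= -950)
  expect_equal(ps$truth$emphysema_pct, 100 * n_low / n_lung)
  expect_lt(abs(ps$truth$emphysema_pct - 15), 2)

  # and at the default (finer) grid the tolerance tightens to 1 pp
  ps2 <- generate_phantom(phantom_spec(noise_sigma_hu = 0))
  expect_lt(abs(ps2$truth$emphysema_pct - 15), 1)
})

test_that("identical specs give bit-identical paired volumes", {
  a <- generate_phantom(small_spec(noise_sigma_hu = 25))
  b <- generate_phantom(small_spec(noise_sigma_hu = 25))
  expect_identical(a$tnc$voxels, b$tnc$voxels)
  expect_identical(a$vnc$voxels, b$vnc$voxels)
  c <- generate_phantom(small_spec(noise_sigma_hu = 25, seed = 7L))
  expect_false(identical(a$tnc$voxels, c$tnc$voxels))
})

test_that("labels partition the grid and VNC is TNC plus in-lung offset", {
  spec <- small_spec(vnc_offset_hu = 4)
  ps <- generate_phantom(spec)
  v <- ps$tnc$voxels
  lung <- ps$truth$lung_label
  # every voxel is exterior air, soft tissue, parenchyma or emphysema
  expect_setequal(unique(as.vector(v)),
                  c(-1000, spec$body_hu, spec$parenchyma_hu,
                    spec$emphysema_hu))
  expect_true(all(v[lung] %in% c(spec$parenchyma_hu, spec$emphysema_hu)))
  expect_false(any(v[!lung] == spec$parenchyma_hu))

  dv <- ps$vnc$voxels - ps$tnc$voxels
  expect_true(all(dv[lung] == spec$vnc_offset_hu))
  expect_true(all(dv[!lung] == 0))
})

test_that("invalid geometry and metadata are rejected", {
  expect_error(small_spec(lung_centers = list(c(0, 0, -90), c(0, 0, 90))),
               "inside the body ellipse")
  expect_error(small_spec(parenchyma_hu = -960), "emphysema_hu < -950")
  expect_error(phantom_spec(voxel_spacing = c(0.9, 0, 1.6)), "spacing")
  expect_error(generate_phantom(small_spec(),
                                patient_meta = list(time_gap_days = 100)),
               "time_gap_days")
})

test_that("unattainable fraction warns and reports the achieved value", {
  spec <- small_spec(emphysema_fraction = 0.9)
  expect_warning(ps <- generate_phantom(spec), "unattainable")
  expect_lt(ps$truth$emphysema_pct, 90)
  expect_gt(ps$truth$emphysema_pct, 0)
})

test_that("analytic truth: water cylinder and ellipse DW in closed form", {
  cyl <- analytic_truth(water_spec(c(100, 100)))
  expect_equal(cyl$analytic_dw_mm, 200, tolerance = 1e-12)
  ell <- analytic_truth(water_spec(c(100, 64)))
  expect_equal(ell$analytic_dw_mm, 2 * sqrt(100 * 64), tolerance = 1e-12)
})

test_that("analytic DW with lungs matches fine-grid numerical integration", {
  spec <- small_spec(parenchyma_hu = -850, emphysema_fraction = 0)
  at <- analytic_truth(spec)
  # oracle: rasterize the central slice at 0.5 mm and integrate HU/1000 + 1
  h <- 0.5
  co <- seq(-160 + h / 2, 160 - h / 2, by = h)
  Y <- matrix(co, length(co), length(co))
  X <- t(Y)
  hu <- matrix(-1000, length(co), length(co))
  hu[(Y / spec$body_semi_axes[1])^2 + (X / spec$body_semi_axes[2])^2 <= 1] <-
    spec$body_hu
  for (i in 1:2) {
    ce <- spec$lung_centers[[i]]; ax <- spec$lung_semi_axes[[i]]
    z <- 0.75  # central-slice voxel centre of the 24-slice, 1.5 mm grid
    s2 <- 1 - ((z - ce[1]) / ax[1])^2
    hu[((Y - ce[2]) / ax[2])^2 + ((X - ce[3]) / ax[3])^2 <= s2] <- -850
  }
  aw <- sum(pmax(hu / 1000 + 1, 0)) * h^2
  dw_oracle <- 2 * sqrt(aw / pi)
  expect_equal(at$dw_per_slice_mm[13], dw_oracle, tolerance = 0.005)
})

test_that("lung volume truth equals the ellipsoid closed form", {
  spec <- small_spec()
  at <- analytic_truth(spec)
  expect_equal(at$lung_volume_cm3,
               2 * 4 / 3 * pi * 14 * 55 * 38 / 1000, tolerance = 1e-12)
  ps <- generate_phantom(spec)
  expect_lt(abs(ps$truth$lung_volume_cm3 - at$lung_volume_cm3) /
              at$lung_volume_cm3, 0.02)
})
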