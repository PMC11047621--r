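test_that("water-equivalent area follows the TG-220 pixel sum", {
  water <- matrix(0, 100, 100)
  expect_equal(water_equivalent_area_slice(water, 1), 10000)
  air <- matrix(-1000, 100, 100)
  expect_equal(water_equivalent_area_slice(air, 1), 0)
  half <- matrix(c(rep(0, 5000), rep(-500, 5000)), 100, 100)
  expect_equal(water_equivalent_area_slice(half, 1), 7500)
  # clamp: below -1000 HU contributes zero, not negative area
  expect_equal(water_equivalent_area_slice(matrix(-1024, 10, 10), 1), 0)
  expect_error(water_equivalent_area_slice(array(0, c(2, 2, 2)), 1), "2-D")
})

test_that("DW closed forms and rasterized water shapes agree", {
  expect_equal(dw_slice(matrix(0, 100, 100), 1), 2 * sqrt(10000 / pi))

  ps <- generate_phantom(water_spec(c(100, 100)))
  d <- dw_volume(ps$tnc)
  expect_lt(abs(d$dw_mean_mm - 200) / 200, 0.01)
  expect_lt(max(d$dw_per_slice_mm) - min(d$dw_per_slice_mm), 1e-9)

  pe <- generate_phantom(water_spec(c(100, 64)))
  de <- dw_volume(pe$tnc)
  expect_lt(abs(de$dw_mean_mm - 160) / 160, 0.01)
})

test_that("DW is air-padding invariant and scales under magnification", {
  sl <- matrix(-1000, 60, 60)
  sl[20:40, 20:40] <- 0
  base <- dw_slice(sl, 1)
  padded <- matrix(-1000, 100, 100)
  padded[21:80, 21:80] <- sl
  expect_equal(dw_slice(padded, 1), base)
  # isotropic x2 magnification: same pattern, 4x pixel area
  expect_equal(dw_slice(sl, 4), 2 * base)
})

test_that("volume DW averages per-slice values, including degenerate cases", {
  # linear taper: per-slice analytic water areas
  nz <- 5L
  arr <- array(-1000, c(nz, 40L, 40L))
  side <- c(6, 10, 14, 18, 22)
  for (k in seq_len(nz)) arr[k, seq_len(side[k]), seq_len(side[k])] <- 0
  vol <- ct_volume(arr, c(1, 1, 1))
  d <- dw_volume(vol)
  expect_equal(d$dw_per_slice_mm, 2 * sqrt(side^2 / pi))
  expect_equal(d$dw_mean_mm, mean(2 * sqrt(side^2 / pi)))
  expect_true(d$dw_mean_mm >= min(d$dw_per_slice_mm) &&
                d$dw_mean_mm <= max(d$dw_per_slice_mm))

  single <- ct_volume(array(arr[3, , ], c(1L, 40L, 40L)), c(1, 1, 1))
  expect_equal(dw_volume(single)$dw_mean_mm, d$dw_per_slice_mm[3])
})

test_that("SSDE is the dose index times the exponential size factor", {
  expect_equal(ssde(5, 250, coeffs = list(a = 1, b = 0)), 5)
  co <- ssde_coefficients()
  dws <- seq(150, 400, by = 10)
  vals <- ssde(5, dws, coeffs = co)
  expect_true(all(diff(vals) < 0))
  # f(DW) = 1 exactly at DW = ln(a)/b
  dw1 <- log(co$a) / co$b
  expect_equal(ssde(7.3, dw1, coeffs = co), 7.3)
  expect_error(ssde(5, 0), "positive")
  expect_error(ssde(-1, 200), "non-negative")
})
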