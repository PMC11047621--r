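test_that("median filter removes isolated outliers and preserves plateaus", {
  ps <- generate_phantom(small_spec())
  m <- segment_lungs(ps$tnc)
  expect_error(suppress_noise(ps$tnc, m, kernel_voxels = 4L), "odd")

  # single +500 HU outlier deep inside parenchyma is erased
  lungpar <- ps$truth$lung_label & !ps$truth$emphysema_label
  # pick an interior parenchyma voxel (all 26 neighbours parenchyma)
  idx <- which(lungpar, arr.ind = TRUE)
  interior <- NULL
  for (i in seq_len(nrow(idx))) {
    nb <- expand.grid(z = idx[i, 1] + (-1:1), y = idx[i, 2] + (-1:1),
                      x = idx[i, 3] + (-1:1))
    if (all(lungpar[as.matrix(nb)])) { interior <- idx[i, ]; break }
  }
  vol <- ps$tnc
  vol$voxels[interior[1], interior[2], interior[3]] <-
    vol$voxels[interior[1], interior[2], interior[3]] + 500
  filt <- suppress_noise(vol, m)
  expect_equal(filt$voxels[interior[1], interior[2], interior[3]],
               ps$spec$parenchyma_hu)

  # noise-free: out-of-mask voxels untouched; interior plateau invariant
  filt0 <- suppress_noise(ps$tnc, m)
  expect_identical(filt0$voxels[!m$mask], ps$tnc$voxels[!m$mask])
  expect_equal(filt0$voxels[interior[1], interior[2], interior[3]],
               ps$spec$parenchyma_hu)
})

test_that("filtering brings noisy LAV closer to the ground truth", {
  ps <- generate_phantom(phantom_spec(seed = 7L))  # sigma 40 default
  m <- segment_lungs(ps$tnc)
  raw <- emphysema_metrics(ps$tnc, m, qct_config(noise_suppression = FALSE))
  filt <- emphysema_metrics(ps$tnc, m, qct_config(noise_suppression = TRUE))
  truth <- ps$truth$emphysema_pct
  expect_lt(abs(filt$lav_pct - truth), abs(raw$lav_pct - truth))
})

test_that("histogram conserves counts and matches the voxel-sort quantile", {
  ps <- generate_phantom(small_spec(noise_sigma_hu = 15))
  m <- segment_lungs(ps$tnc)
  h <- attenuation_histogram(ps$tnc, m, bin_width_hu = 1)
  expect_identical(sum(h$counts), h$total_voxels)
  expect_identical(h$total_voxels, sum(m$mask))

  x <- ps$tnc$voxels[m$mask]
  for (p in c(5, 10, 15, 50, 90))
    expect_lt(abs(percentile_density(h, p) - percentile_density(x, p)), 1)

  # uniform lung: single nonzero bin, percentile equals the constant
  u <- ps$tnc
  u$voxels[m$mask] <- -850
  hu <- attenuation_histogram(u, m)
  expect_identical(sum(hu$counts > 0), 1L)
  for (p in c(10, 15, 50)) {
    expect_equal(percentile_density(hu, p), -850)
    expect_equal(percentile_density(u$voxels[m$mask], p), -850)
  }
})

test_that("percentile density equals the sort oracle on a known mixture", {
  set.seed(3)
  x <- c(rnorm(300, -980, 15), rnorm(700, -860, 25))
  for (p in c(10, 15, 30, 50)) {
    expect_identical(percentile_density(x, p),
                     sort(x)[ceiling(p / 100 * length(x))])
  }
  expect_lte(percentile_density(x, 10), percentile_density(x, 15))
  expect_error(percentile_density(numeric(0), 10), "empty")
  expect_error(percentile_density(x, 0), "p must be")
})

test_that("LAV is inclusive at the threshold, conserved and monotone", {
  ps <- generate_phantom(small_spec())
  m <- segment_lungs(ps$tnc)

  u <- ps$tnc
  u$voxels[m$mask] <- -980
  expect_equal(lav(u, m)$lav_pct, 100)
  u$voxels[m$mask] <- -850
  expect_equal(lav(u, m)$lav_pct, 0)
  u$voxels[m$mask] <- -950  # inclusive: "-950 HU and less"
  expect_equal(lav(u, m)$lav_pct, 100)

  # conservation: below + above = lung volume
  lv <- lav(ps$tnc, m)
  n_above <- sum(ps$tnc$voxels[m$mask] > -950)
  expect_equal(lv$lav_cm3 + n_above * m$voxel_volume_cm3,
               mask_volume_cm3(m))
  # monotone in threshold
  lavs <- vapply(c(-1000, -975, -950, -925, -900),
                 function(t) lav(ps$tnc, m, t)$lav_cm3, numeric(1))
  expect_true(all(diff(lavs) >= 0))
})

test_that("global HU shift moves percentiles exactly and never raises LAV", {
  ps <- generate_phantom(small_spec(noise_sigma_hu = 20))
  m <- segment_lungs(ps$tnc)
  cfg <- qct_config()  # noise suppression on: shift must commute with it
  base <- emphysema_metrics(ps$tnc, m, cfg)
  shifted <- ps$tnc
  shifted$voxels[m$mask] <- shifted$voxels[m$mask] + 10
  em <- emphysema_metrics(shifted, m, cfg)
  expect_equal(em$pd_hu[["pd10_hu"]], base$pd_hu[["pd10_hu"]] + 10)
  expect_equal(em$pd_hu[["pd15_hu"]], base$pd_hu[["pd15_hu"]] + 10)
  expect_lte(em$lav_cm3, base$lav_cm3)
})

test_that("metric bundle is consistent with its parts and ground truth", {
  ps <- generate_phantom(small_spec())
  m <- segment_lungs(ps$tnc)
  em <- emphysema_metrics(ps$tnc, m, qct_config(noise_suppression = FALSE))
  expect_equal(em$lung_volume_cm3, mask_volume_cm3(m))
  expect_identical(em$pvol_cm3[["pvol15_cm3"]], 0.15 * em$lung_volume_cm3)
  expect_identical(em$pvol_cm3[["pvol10_cm3"]], 0.10 * em$lung_volume_cm3)
  expect_lt(abs(em$lav_pct - ps$truth$emphysema_pct), 1)
  expect_equal(em$pd_hu[["pd10_hu"]],
               ps$truth$targets$tnc$pd10_hu)
  # pipeline wiring: with zero noise the filter only acts at cluster
  # boundaries, trimming the LAV slightly on this coarse test grid
  em_f <- emphysema_metrics(ps$tnc, m, qct_config(noise_suppression = TRUE))
  expect_lte(em_f$lav_pct, em$lav_pct)
  expect_lt(abs(em_f$lav_pct - em$lav_pct), 2)
})
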