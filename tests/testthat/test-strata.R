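# build a cohort table directly (no imaging) with a known disagreement
# structure: the VNC deficit is injected only above the DW cut
synth_table <- function(n_low = 40, n_high = 40, effect_high = -5,
                        effect_low = 0, seed = 19) {
  set.seed(seed)
  n <- n_low + n_high
  dw <- c(runif(n_low, 200, 265), runif(n_high, 275, 330))
  tnc <- rnorm(n, 100, 15)
  eff <- c(rep(effect_low, n_low), rep(effect_high, n_high))
  vnc <- tnc + eff + rnorm(n, 0, 0.8)
  data.frame(
    patient_id = sprintf("S%03d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(runif(n, 20, 85)),
    bmi = rnorm(n, 26, 4),
    contrast_phase = sample(c("PAP", "PVP"), n, replace = TRUE,
                            prob = c(0.2, 0.8)),
    iodine_g = rnorm(n, 27, 6),
    iodine_per_weight = rnorm(n, 0.35, 0.08),
    time_gap_days = sample(0:54, n, replace = TRUE),
    dw_mean_mm = dw,
    ssde_mgy = rnorm(n, 4, 1.5),
    lav_cm3_tnc = tnc, lav_cm3_vnc = vnc)
}

test_that("injected DW-dependent disagreement is detected between strata", {
  tab <- synth_table()
  res <- stratified_compare(tab, "lav_cm3")
  ct <- res$contrasts[res$contrasts$split == "dw", ]
  expect_identical(ct$n_a + ct$n_b, 80L)
  expect_lt(ct$p, 0.05)
  per <- res$per_stratum[res$per_stratum$split == "dw", ]
  hi <- per[per$stratum == ">270", ]
  lo <- per[per$stratum == "<270", ]
  expect_lt(hi$median_diff, -3)
  expect_lt(hi$p, 0.05)
  expect_gt(lo$p, 0.05)
})

test_that("single-stratum splits report the contrast as not applicable", {
  tab <- synth_table(n_low = 20, n_high = 0)
  suppressWarnings(res <- stratified_compare(tab, "lav_cm3"))
  ct <- res$contrasts[res$contrasts$split == "dw", ]
  expect_true(is.na(ct$U))
  expect_true(is.na(ct$p))
})

test_that("stratum counts partition the cohort minus missing rows", {
  tab <- synth_table()
  tab$bmi[c(3, 9)] <- NA
  tab$bmi[tab$bmi < 18.5 & !is.na(tab$bmi)] <- 17  # force an excluded band
  res <- stratified_compare(tab, "lav_cm3")
  per <- res$per_stratum
  for (sp in c("sex", "contrast_phase", "ssde", "bmi")) {
    ct <- res$contrasts[res$contrasts$split == sp, ]
    expect_identical(sum(per$n[per$split == sp]) + ct$missing, nrow(tab))
  }
  # age bands exclude the middle range by design
  agect <- res$contrasts[res$contrasts$split == "age", ]
  expect_identical(sum(per$n[per$split == "age"]) + agect$missing, nrow(tab))
})

test_that("missing metric columns and empty tables are rejected", {
  tab <- synth_table()
  expect_error(stratified_compare(tab, "pd15_hu"), "metric columns")
  expect_error(stratified_compare(tab[0, ], "lav_cm3"))
})
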