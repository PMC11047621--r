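#' Confounder stratification configuration
#'
#' Declares the subgroup splits of the cohort used to probe what drives
#' TNC/VNC disagreement. Each split is either a `"category"` (use the
#' variable's values as strata), a `"cut"` (two strata below/above a cut
#' point), `"bands"` (named, possibly non-exhaustive intervals; rows
#' outside all bands are excluded from that split), or `"median"` (cut at
#' the cohort median). Defaults: sex and contrast phase as categories;
#' water-equivalent diameter cut at 270 mm; SSDE cut at 3.2 mGy; BMI bands
#' normal 18.5-25 and elevated >25 kg/m^2; age bands younger <50 and older
#' >69 years; iodine amount, iodine/weight and acquisition time gap as
#' median splits.
#'
#' @param splits named list describing the splits; see Details above. Each
#'   entry is `list(var = <column>, type = <type>, cut = <num>,
#'   bands = list(name = c(lo, hi)))` with `cut`/`bands` as applicable.
#' @return object of class `strata_config`.
#' @export
strata_config <- function(splits = NULL) {
  if (is.null(splits)) {
    splits <- list(
      sex = list(var = "sex", type = "category"),
      age = list(var = "age", type = "bands",
                 bands = list(younger = c(-Inf, 50), older = c(69, Inf))),
      time_gap = list(var = "time_gap_days", type = "median"),
      contrast_phase = list(var = "contrast_phase", type = "category"),
      iodine = list(var = "iodine_g", type = "median"),
      iodine_per_weight = list(var = "iodine_per_weight", type = "median"),
      ssde = list(var = "ssde_mgy", type = "cut", cut = 3.2),
      bmi = list(var = "bmi", type = "bands",
                 bands = list(normal = c(18.5, 25), elevated = c(25, Inf))),
      dw = list(var = "dw_mean_mm", type = "cut", cut = 270))
  }
  for (s in splits)
    stopifnot(s$type %in% c("category", "cut", "bands", "median"))
  structure(list(splits = splits), class = "strata_config")
}

# factor of stratum membership (NA = excluded from this split)
assign_strata <- function(values, split) {
  switch(split$type,
    category = factor(values),
    cut = {
      f <- ifelse(values < split$cut, paste0("<", split$cut),
                  ifelse(values > split$cut, paste0(">", split$cut), NA))
      factor(f, levels = c(paste0("<", split$cut), paste0(">", split$cut)))
    },
    median = {
      cut <- median(values, na.rm = TRUE)
      f <- ifelse(values <= cut, "low", "high")
      factor(f, levels = c("low", "high"))
    },
    bands = {
      f <- rep(NA_character_, length(values))
      for (nm in names(split$bands)) {
        b <- split$bands[[nm]]
        f[!is.na(values) & values > b[1] & values <= b[2]] <- nm
      }
      factor(f, levels = names(split$bands))
    })
}

#' Stratified paired comparison of a metric
#'
#' For one metric, runs the paired TNC-vs-VNC Wilcoxon within each stratum
#' of every configured split, and contrasts the two strata of a binary
#' split with a Mann-Whitney U test on the per-patient differences
#' (VNC - TNC) — the confounder analysis pattern. Rows missing the stratum
#' variable are excluded from that split and counted; strata with no pairs
#' are skipped with a warning; a split with fewer than two populated
#' strata reports the between-strata contrast as not applicable.
#'
#' @param table cohort table (one row per pair) with columns
#'   `<metric>_tnc`, `<metric>_vnc` and the stratum variables.
#' @param metric base metric name, e.g. `"lav_cm3"`.
#' @param strata a [strata_config()].
#' @return object of class `stratified_comparison`: `per_stratum`
#'   data.frame (split, stratum, n, median_diff, p, r), `contrasts`
#'   data.frame (split, U, p, n per stratum, missing count), and the
#'   whole-cohort [paired_compare()] under `overall`.
#' @export
stratified_compare <- function(table, metric, strata = strata_config()) {
  stopifnot(nrow(table) > 0)
  ctnc <- paste0(metric, "_tnc"); cvnc <- paste0(metric, "_vnc")
  if (!all(c(ctnc, cvnc) %in% names(table)))
    stop("metric columns not found: ", ctnc, ", ", cvnc)
  x <- table[[ctnc]]; y <- table[[cvnc]]
  diffs <- y - x

  per <- list(); ctr <- list()
  for (nm in names(strata$splits)) {
    sp <- strata$splits[[nm]]
    if (!sp$var %in% names(table)) next
    f <- assign_strata(table[[sp$var]], sp)
    missing_n <- sum(is.na(f))
    lev_used <- character(0)
    for (lev in levels(f)) {
      sel <- !is.na(f) & f == lev
      if (!any(sel)) {
        warning(sprintf("split '%s': stratum '%s' has no pairs; skipped",
                        nm, lev))
        next
      }
      lev_used <- c(lev_used, lev)
      pc <- paired_compare(x[sel], y[sel], metric)
      per[[length(per) + 1L]] <- data.frame(
        split = nm, stratum = lev, n = pc$n,
        median_diff = pc$median_of_differences,
        p = pc$p_value, r = pc$pairing_r)
    }
    if (length(lev_used) == 2L) {
      g1 <- diffs[!is.na(f) & f == lev_used[1]]
      g2 <- diffs[!is.na(f) & f == lev_used[2]]
      mw <- mann_whitney_u(g1, g2)
      ctr[[length(ctr) + 1L]] <- data.frame(
        split = nm, stratum_a = lev_used[1], stratum_b = lev_used[2],
        n_a = length(g1), n_b = length(g2), missing = missing_n,
        U = mw$statistic, p = mw$p_value)
    } else {
      ctr[[length(ctr) + 1L]] <- data.frame(
        split = nm, stratum_a = if (length(lev_used)) lev_used[1] else NA,
        stratum_b = NA, n_a = NA_integer_, n_b = NA_integer_,
        missing = missing_n, U = NA_real_, p = NA_real_)
    }
  }
  structure(list(
    metric = metric,
    overall = paired_compare(x, y, metric),
    per_stratum = do.call(rbind, per),
    contrasts = do.call(rbind, ctr)),
    class = "stratified_comparison")
}

#' @export
print.stratified_comparison <- function(x, ...) {
  cat(sprintf("<stratified_comparison> metric %s\n", x$metric))
  print(x$overall)
  cat("per-stratum paired tests:\n")
  print(x$per_stratum, row.names = FALSE)
  cat("between-strata contrasts (Mann-Whitney on differences):\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
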