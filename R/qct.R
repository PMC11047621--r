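#' Configuration of the emphysema metric pipeline
#'
#' @param noise_suppression apply the in-mask median filter before the
#'   histogram metrics (default on, as in routine vendor workflows)?
#' @param kernel_voxels odd median-filter kernel edge length in voxels.
#' @param threshold_hu emphysema threshold; voxels at or below it count as
#'   low-attenuation volume (LAV). Default -950 HU.
#' @param percentiles percentile-density levels evaluated (percent).
#' @param bin_width_hu histogram bin width, HU.
#' @return a list of class `qct_config`.
#' @export
qct_config <- function(noise_suppression = TRUE, kernel_voxels = 3L,
                       threshold_hu = -950, percentiles = c(10, 15),
                       bin_width_hu = 1) {
  structure(list(noise_suppression = isTRUE(noise_suppression),
                 kernel_voxels = as.integer(kernel_voxels),
                 threshold_hu = threshold_hu,
                 percentiles = percentiles,
                 bin_width_hu = bin_width_hu),
            class = "qct_config")
}

#' In-mask median noise suppression
#'
#' Replaces each in-mask voxel by the median of the in-mask voxels in a
#' `kernel^3` neighbourhood (clipped at the volume border); out-of-mask
#' voxels pass through unchanged. Deterministic; the standard qCT
#' stand-in for the unspecified noise-suppression functions of vendor
#' COPD tools.
#'
#' @param vol a [ct_volume].
#' @param mask a `lung_mask` (or logical array congruent with `vol`).
#' @param kernel_voxels odd kernel edge length.
#' @return a filtered [ct_volume].
#' @export
suppress_noise <- function(vol, mask, kernel_voxels = 3L) {
  stopifnot(inherits(vol, "ct_volume"))
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(vol$voxels)))
  if (kernel_voxels %% 2L == 0L || kernel_voxels < 1L)
    stop("kernel_voxels must be odd (median centre undefined otherwise)")
  out <- vol
  out$voxels <- array(
    cpp_median_filter3(as.numeric(vol$voxels), as.logical(m),
                       dim(vol$voxels), as.integer(kernel_voxels)),
    dim(vol$voxels))
  out
}

#' Attenuation histogram over the lung mask
#'
#' @param vol a [ct_volume].
#' @param mask a `lung_mask` or logical array.
#' @param bin_width_hu bin width in HU. Bins are left-closed right-open,
#'   except the last which is closed; edges span \[-1024, 3071\].
#' @return object of class `density_histogram` with `bin_edges`, `counts`,
#'   `total_voxels`, `voxel_volume_cm3`.
#' @export
attenuation_histogram <- function(vol, mask, bin_width_hu = 1) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  x <- vol$voxels[m]
  if (length(x) == 0L) stop("empty mask: no voxels to histogram")
  lo <- -1024
  nbin <- ceiling((3071 - lo) / bin_width_hu)
  edges <- lo + bin_width_hu * (0:nbin)
  idx <- pmin(pmax(floor((x - lo) / bin_width_hu) + 1, 1), nbin)
  structure(list(bin_edges = edges,
                 counts = tabulate(idx, nbins = nbin),
                 total_voxels = length(x),
                 voxel_volume_cm3 = voxel_volume_cm3(vol)),
            class = "density_histogram")
}

#' Low-attenuation volume (LAV)
#'
#' The emphysema proxy: volume of in-mask voxels at or below the
#' threshold (inclusive), in cm^3 and as a percentage of the lung volume.
#'
#' @param vol a [ct_volume].
#' @param mask a `lung_mask` or logical array.
#' @param threshold_hu inclusive threshold, default -950 HU.
#' @return list with `lav_cm3` and `lav_pct`.
#' @export
lav <- function(vol, mask, threshold_hu = -950) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  x <- vol$voxels[m]
  if (length(x) == 0L) stop("empty mask: LAV undefined")
  vv <- voxel_volume_cm3(vol)
  n <- sum(x <= threshold_hu)
  list(lav_cm3 = n * vv, lav_pct = 100 * n / length(x))
}

#' Percentile density of the lung attenuation distribution
#'
#' The smallest HU value `h` such that at least `p` percent of in-mask
#' voxels are at or below `h` (lower empirical quantile, no interpolation;
#' ties resolve toward lower HU). Low percentiles (10th, 15th) proxy
#' pre-emphysema. Dispatches on raw voxel vectors and on
#' [attenuation_histogram()] objects; the two paths agree within one bin
#' width.
#'
#' @param x numeric vector of in-mask HU values, or a `density_histogram`.
#' @param p percentile in (0, 100).
#' @return HU value.
#' @export
percentile_density <- function(x, p) UseMethod("percentile_density")

#' @export
percentile_density.default <- function(x, p) {
  if (length(x) == 0L) stop("empty distribution: percentile undefined")
  if (p <= 0 || p >= 100) stop("p must be in (0, 100)")
  sort(x)[ceiling(p / 100 * length(x))]
}

#' @export
percentile_density.density_histogram <- function(x, p) {
  if (p <= 0 || p >= 100) stop("p must be in (0, 100)")
  cum <- cumsum(x$counts)
  i <- which(cum >= p / 100 * x$total_voxels)[1]
  x$bin_edges[i]
}

#' Emphysema and pre-emphysema metrics of one volume
#'
#' Bundles the metric panel computed from the masked attenuation
#' distribution: LAV in cm^3 and percent at the configured threshold,
#' percentile densities (HU at the 10th/15th percentile), the definitional
#' percentile volumes (N% of the lung volume, the cm^3 reading of the
#' percentile metrics), and the lung volume. Noise suppression is applied
#' first when the config says so (the default).
#'
#' @param vol a [ct_volume].
#' @param mask a `lung_mask` from [segment_lungs()].
#' @param config a [qct_config()].
#' @return object of class `emphysema_metrics`.
#' @export
emphysema_metrics <- function(vol, mask, config = qct_config()) {
  stopifnot(inherits(mask, "lung_mask"))
  if (config$noise_suppression)
    vol <- suppress_noise(vol, mask, config$kernel_voxels)
  x <- vol$voxels[mask$mask]
  if (length(x) == 0L) stop("empty mask: metrics undefined")
  lung_cm3 <- mask_volume_cm3(mask)
  lv <- lav(vol, mask, config$threshold_hu)
  pd <- vapply(config$percentiles, function(p) percentile_density(x, p),
               numeric(1))
  pvol <- config$percentiles / 100 * lung_cm3
  out <- list(lav_cm3 = lv$lav_cm3, lav_pct = lv$lav_pct,
              threshold_hu = config$threshold_hu,
              percentiles = config$percentiles,
              pd_hu = pd, pvol_cm3 = pvol,
              lung_volume_cm3 = lung_cm3,
              noise_suppression = config$noise_suppression)
  names(out$pd_hu) <- paste0("pd", config$percentiles, "_hu")
  names(out$pvol_cm3) <- paste0("pvol", config$percentiles, "_cm3")
  structure(out, class = "emphysema_metrics")
}

#' @export
print.emphysema_metrics <- function(x, ...) {
  cat("<emphysema_metrics>\n")
  cat(sprintf("  lung volume : %.1f cm^3\n", x$lung_volume_cm3))
  cat(sprintf("  LAV (<= %.0f HU): %.1f cm^3 (%.2f%%)\n",
              x$threshold_hu, x$lav_cm3, x$lav_pct))
  for (i in seq_along(x$percentiles))
    cat(sprintf("  PD%-2d: %.0f HU   (percentile volume %.1f cm^3)\n",
                x$percentiles[i], x$pd_hu[i], x$pvol_cm3[i]))
  invisible(x)
}

#' One metrics row for the cohort table
#'
#' @param m an `emphysema_metrics` object.
#' @param suffix column suffix (`"tnc"` or `"vnc"`).
#' @return a one-row data.frame.
#' @keywords internal
metrics_row <- function(m, suffix) {
  df <- data.frame(lav_cm3 = m$lav_cm3, lav_pct = m$lav_pct,
                   pd10_hu = m$pd_hu[["pd10_hu"]],
                   pd15_hu = m$pd_hu[["pd15_hu"]],
                   pvol10_cm3 = m$pvol_cm3[["pvol10_cm3"]],
                   pvol15_cm3 = m$pvol_cm3[["pvol15_cm3"]],
                   lung_volume_cm3 = m$lung_volume_cm3)
  names(df) <- paste0(names(df), "_", suffix)
  df
}
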