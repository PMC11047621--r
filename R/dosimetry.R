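# Water-equivalent diameter (AAPM TG-220) and size-specific dose estimate.

#' Water-equivalent area of one axial slice
#'
#' The TG-220 relation: each pixel contributes
#' `max(HU/1000 + 1, 0) x pixel area`, summed over the full slice. Air
#' (-1000 HU) contributes zero, so no body-contour ROI is needed; the
#' clamp at zero keeps pathological voxels below -1000 HU from producing
#' negative area.
#'
#' @param slice_hu 2-D matrix of HU values.
#' @param pixel_area_mm2 in-plane pixel area, mm^2.
#' @return water-equivalent area in mm^2.
#' @export
water_equivalent_area_slice <- function(slice_hu, pixel_area_mm2) {
  if (!is.matrix(slice_hu)) stop("slice_hu must be a 2-D matrix")
  sum(pmax(slice_hu / 1000 + 1, 0)) * pixel_area_mm2
}

#' Water-equivalent diameter of one slice
#'
#' Diameter of the water cylinder with the same integrated attenuation:
#' `DW = 2 * sqrt(A_w / pi)`.
#'
#' @inheritParams water_equivalent_area_slice
#' @return DW in mm.
#' @export
dw_slice <- function(slice_hu, pixel_area_mm2) {
  2 * sqrt(water_equivalent_area_slice(slice_hu, pixel_area_mm2) / pi)
}

#' Per-slice and mean water-equivalent diameter of a volume
#'
#' Computes DW for every axial slice and the arithmetic mean over slices,
#' the per-study summary used to stratify patients by body size.
#'
#' @param vol a [ct_volume].
#' @return object of class `dosimetry_result` with `dw_per_slice_mm`,
#'   `dw_mean_mm`, `ctdi_vol_mgy` (carried from the volume), and `ssde_mgy`
#'   unset until [ssde()] is applied.
#' @export
dw_volume <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  if (any(d == 0L)) stop("empty volume: DW undefined")
  pa <- vol$spacing[2] * vol$spacing[3]
  dws <- vapply(seq_len(d[1]), function(k)
    dw_slice(matrix(vol$voxels[k, , ], d[2], d[3]), pa), numeric(1))
  structure(list(dw_per_slice_mm = dws, dw_mean_mm = mean(dws),
                 ctdi_vol_mgy = vol$ctdi_vol_mgy,
                 ssde_mgy = NA_real_, conversion_factor = NA_real_),
            class = "dosimetry_result")
}

#' Size-specific dose estimate conversion coefficients
#'
#' The SSDE conversion factor is `f(DW) = a * exp(-b * DW)`. Defaults are
#' the 32-cm-body-phantom fit of the AAPM size-specific-dose reports
#' (a = 3.704369, b = 0.003671937 per mm); `"head16cm"` selects the 16-cm
#' head-phantom fit. Both are configuration values, overridable per study.
#'
#' @param phantom `"body32cm"` (default) or `"head16cm"`.
#' @return list with `a` and `b`.
#' @export
ssde_coefficients <- function(phantom = c("body32cm", "head16cm")) {
  switch(match.arg(phantom),
         body32cm = list(a = 3.704369, b = 0.003671937),
         head16cm = list(a = 1.874799, b = 0.03871313))
}

#' Size-specific dose estimate
#'
#' `SSDE = CTDIvol x a * exp(-b * DW)`: the scanner dose index rescaled by
#' a patient-size-dependent conversion factor.
#'
#' @param ctdi_vol_mgy volumetric CT dose index, mGy (>= 0).
#' @param dw_mm water-equivalent diameter, mm (> 0).
#' @param coeffs conversion coefficients, see [ssde_coefficients()].
#' @return SSDE in mGy.
#' @export
ssde <- function(ctdi_vol_mgy, dw_mm, coeffs = ssde_coefficients()) {
  if (any(dw_mm <= 0)) stop("dw_mm must be positive")
  if (any(ctdi_vol_mgy < 0)) stop("ctdi_vol_mgy must be non-negative")
  ctdi_vol_mgy * coeffs$a * exp(-coeffs$b * dw_mm)
}

#' Full dosimetry of a volume
#'
#' [dw_volume()] plus, when the volume carries a CTDIvol, the SSDE.
#'
#' @param vol a [ct_volume].
#' @param coeffs see [ssde_coefficients()].
#' @return a `dosimetry_result` with `ssde_mgy` filled in when possible.
#' @export
dosimetry <- function(vol, coeffs = ssde_coefficients()) {
  res <- dw_volume(vol)
  if (is.finite(res$ctdi_vol_mgy)) {
    res$conversion_factor <- coeffs$a * exp(-coeffs$b * res$dw_mean_mm)
    res$ssde_mgy <- res$ctdi_vol_mgy * res$conversion_factor
  }
  res
}

#' @export
print.dosimetry_result <- function(x, ...) {
  cat(sprintf("<dosimetry_result> mean DW %.1f mm over %d slices (range %.1f-%.1f)\n",
              x$dw_mean_mm, length(x$dw_per_slice_mm),
              min(x$dw_per_slice_mm), max(x$dw_per_slice_mm)))
  if (is.finite(x$ssde_mgy))
    cat(sprintf("  CTDIvol %.2f mGy x f=%.3f -> SSDE %.2f mGy\n",
                x$ctdi_vol_mgy, x$conversion_factor, x$ssde_mgy))
  invisible(x)
}
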