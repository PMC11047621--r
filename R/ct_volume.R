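#' CT volume container
#'
#' A `ct_volume` holds a 3-D array of Hounsfield-unit (HU) voxel values in
#' `(slice, row, column)` axis order together with the geometry and dose
#' metadata needed downstream: voxel spacing in mm per axis, a world origin
#' in mm, and optionally the scanner-reported CTDIvol in mGy.
#'
#' @param voxels 3-D numeric array of HU values, dimensions `(slice, row,
#'   column)`.
#' @param spacing numeric length-3, mm per axis in `(slice, row, column)`
#'   order. All entries must be positive.
#' @param origin numeric length-3, world coordinates of the first voxel in
#'   mm. Defaults to `c(0, 0, 0)`.
#' @param ctdi_vol_mgy scanner-reported volumetric CT dose index in mGy, or
#'   `NA` when unknown.
#' @param identifier character label for the volume.
#' @param clamp clamp HU to the 12-bit CT range \[-1024, 3071\]? Applied by
#'   the readers; defaults to `FALSE` for in-memory construction.
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      ctdi_vol_mgy = NA_real_, identifier = "volume",
                      clamp = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array (slice, row, column)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (any(!is.finite(voxels)))
    stop("voxels must be finite HU values")
  storage.mode(voxels) <- "double"
  if (clamp) voxels[] <- pmin(pmax(voxels, -1024), 3071)
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         ctdi_vol_mgy = as.numeric(ctdi_vol_mgy)[1],
         identifier = as.character(identifier)[1]),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume '%s'>\n", x$identifier))
  cat(sprintf("  grid    : %d slices x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing : %.3f x %.3f x %.3f mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range: [%.0f, %.0f]\n", min(x$voxels), max(x$voxels)))
  if (is.finite(x$ctdi_vol_mgy))
    cat(sprintf("  CTDIvol : %.2f mGy\n", x$ctdi_vol_mgy))
  invisible(x)
}

#' Voxel volume of a CT grid
#'
#' @param x a `ct_volume` (or anything with a `spacing` field in mm).
#' @return voxel volume in cm^3.
#' @export
voxel_volume_cm3 <- function(x) {
  sp <- if (inherits(x, "ct_volume") || is.list(x)) x$spacing else x
  prod(sp) / 1000
}

#' Validate metadata needed by the analysis pipeline
#'
#' Reports (never raises) problems that would invalidate downstream
#' computations: missing/non-positive spacing, non-finite voxels, and a
#' missing CTDIvol when a size-specific dose estimate is requested.
#'
#' @param vol a [ct_volume].
#' @param require_dose is SSDE going to be computed from this volume?
#' @return character vector of issues; empty when the volume is usable.
#' @export
validate_metadata <- function(vol, require_dose = FALSE) {
  issues <- character(0)
  if (!inherits(vol, "ct_volume"))
    return("not a ct_volume object")
  if (length(vol$spacing) != 3L || any(!is.finite(vol$spacing)) ||
      any(vol$spacing <= 0))
    issues <- c(issues, "spacing must be 3 positive finite values in mm")
  if (any(!is.finite(vol$voxels)))
    issues <- c(issues, "voxel array contains non-finite values")
  rng <- range(vol$voxels)
  if (rng[1] < -1024 || rng[2] > 3071)
    issues <- c(issues, "HU values outside the clamped range [-1024, 3071]")
  if (require_dose && !is.finite(vol$ctdi_vol_mgy))
    issues <- c(issues, "ctdi_vol_mgy missing but SSDE was requested")
  issues
}
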