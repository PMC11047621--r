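#' Lung segmentation parameters
#'
#' Density-based lung extraction: air-like voxels (below `air_threshold_hu`)
#' that are not connected to the in-plane volume border are candidate lung;
#' the largest `keep_components` connected components above
#' `min_component_cm3` are kept and closed morphologically with a spherical
#' element of `closing_radius_mm`. `remove_airways` is reserved for real
#' scans (phantoms have no airway tree) and is not yet implemented.
#'
#' @param air_threshold_hu candidate threshold, HU.
#' @param keep_components number of components to keep (2 lungs).
#' @param min_component_cm3 minimum component volume, cm^3.
#' @param closing_radius_mm morphological closing radius, mm.
#' @param remove_airways reserved flag; must be `FALSE`.
#' @return a list of class `lungseg_params`.
#' @export
lungseg_params <- function(air_threshold_hu = -320, keep_components = 2L,
                           min_component_cm3 = 50, closing_radius_mm = 2,
                           remove_airways = FALSE) {
  if (isTRUE(remove_airways))
    stop("airway removal is reserved but not implemented")
  structure(list(air_threshold_hu = air_threshold_hu,
                 keep_components = as.integer(keep_components),
                 min_component_cm3 = min_component_cm3,
                 closing_radius_mm = closing_radius_mm,
                 remove_airways = FALSE),
            class = "lungseg_params")
}

#' Segment the lungs of a CT volume
#'
#' Thresholds air-like voxels, removes exterior air by discarding
#' components connected to the in-plane border (a per-slice 2-D pass
#' followed by a 3-D 26-connectivity pass), keeps the largest components
#' above the minimum size, and applies morphological closing. This is an
#' explicit, reproducible replacement for the density-based segmentation
#' inside vendor COPD workstations.
#'
#' @param vol a [ct_volume].
#' @param params a [lungseg_params()].
#' @return an object of class `lung_mask`: `mask` (logical array congruent
#'   with the volume), `voxel_volume_cm3`, `component_count`, `params`.
#' @export
segment_lungs <- function(vol, params = lungseg_params()) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  cand <- vol$voxels < params$air_threshold_hu

  # per-slice 2-D pass: drop candidate regions touching the slice border
  for (k in seq_len(d[1])) {
    sl <- array(cand[k, , ], c(1L, d[2], d[3]))
    lab <- array(cpp_label3d(as.logical(sl), dim(sl)), dim(sl))
    border <- unique(c(lab[1, c(1, d[2]), ], lab[1, , c(1, d[3])]))
    border <- border[border > 0L]
    if (length(border)) {
      sl[lab %in% border] <- FALSE
      cand[k, , ] <- sl[1, , ]
    }
  }

  # 3-D pass: component filtering at 26-connectivity
  lab <- array(cpp_label3d(as.logical(cand), d), d)
  border3 <- unique(c(lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  sizes <- tabulate(lab)
  keep <- setdiff(which(sizes > 0), border3[border3 > 0L])
  vv <- voxel_volume_cm3(vol)
  keep <- keep[sizes[keep] * vv >= params$min_component_cm3]
  if (length(keep) == 0L)
    stop(sprintf(
      "empty segmentation: no component above %.0f cm^3 below %.0f HU",
      params$min_component_cm3, params$air_threshold_hu))
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- keep[seq_len(min(params$keep_components, length(keep)))]
  mask <- array(lab %in% keep, d)

  if (params$closing_radius_mm > 0) {
    off <- sphere_offsets(params$closing_radius_mm, vol$spacing)
    mask <- array(cpp_binary_morph(as.logical(mask), d, off, TRUE), d)
    mask <- array(cpp_binary_morph(as.logical(mask), d, off, FALSE), d)
  }

  structure(list(mask = mask, voxel_volume_cm3 = vv,
                 component_count = length(keep), params = params),
            class = "lung_mask")
}

#' Volume of a lung mask in cm^3
#'
#' Voxel count times voxel volume — the denominator of the relative
#' low-attenuation volume.
#'
#' @param mask a [segment_lungs()] result, or a logical array plus
#'   `voxel_volume_cm3`.
#' @param voxel_volume_cm3 required when `mask` is a bare array.
#' @return volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask, voxel_volume_cm3 = NULL) {
  if (inherits(mask, "lung_mask"))
    return(sum(mask$mask) * mask$voxel_volume_cm3)
  stopifnot(!is.null(voxel_volume_cm3))
  sum(mask) * voxel_volume_cm3
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %d voxels (%.1f cm^3) in %d component(s)\n",
              sum(x$mask), mask_volume_cm3(x), x$component_count))
  invisible(x)
}

#' Write a lung mask as NIfTI
#'
#' @param mask a `lung_mask`.
#' @param vol the [ct_volume] it belongs to (for spacing).
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_lung_mask <- function(mask, vol, path) {
  write_ct_volume(
    ct_volume(array(as.numeric(mask$mask), dim(mask$mask)), vol$spacing,
              identifier = paste0(vol$identifier, "-lungmask")),
    path, format = "nifti")
}
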