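#' Read a CT volume from disk
#'
#' Reads either a NIfTI-1 file (`.nii` / `.nii.gz`) or a directory holding a
#' DICOM series (one file per axial slice). DICOM pixel values are mapped to
#' HU via the Rescale Slope/Intercept tags and slices are ordered by spatial
#' position, ascending. HU values are clamped to \[-1024, 3071\] on ingest.
#' A JSON sidecar (`<file>.json` next to a NIfTI, `meta.json` inside a DICOM
#' directory) supplies CTDIvol and the identifier when present.
#'
#' @param path NIfTI file or DICOM series directory.
#' @param format_hint `"auto"` (default), `"nifti"` or `"dicom"`.
#' @return a [ct_volume].
#' @export
read_ct_volume <- function(path, format_hint = c("auto", "nifti", "dicom")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("path does not exist: ", path)
  fmt <- format_hint
  if (fmt == "auto") fmt <- if (dir.exists(path)) "dicom" else "nifti"
  if (fmt == "dicom") return(read_dicom_series(path))

  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  # NIfTI stores (x, y, z) with x fastest; internal order is (slice, row, col)
  arr <- aperm(arr, c(3L, 2L, 1L))
  sp <- RNifti::pixdim(img)
  spacing <- c(sp[3], sp[2], sp[1])
  meta <- read_sidecar(paste0(path, ".json"))
  ct_volume(arr, spacing,
            origin = meta$origin %||% c(0, 0, 0),
            ctdi_vol_mgy = meta$ctdi_vol_mgy %||% NA_real_,
            identifier = meta$identifier %||%
              sub("\\.nii(\\.gz)?$", "", basename(path)),
            clamp = TRUE)
}

#' Write a CT volume to disk
#'
#' Writes NIfTI-1 (with voxel spacing in the header and a JSON sidecar for
#' dose/identity metadata) or a DICOM series directory. HU values are
#' rounded to the nearest integer on write, so integer-HU volumes
#' round-trip losslessly through [read_ct_volume()].
#'
#' @param vol a [ct_volume].
#' @param path output file (NIfTI) or directory (DICOM).
#' @param format `"nifti"` or `"dicom"`.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(vol, path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  stopifnot(inherits(vol, "ct_volume"))
  if (format == "dicom") return(write_dicom_series(vol, path))

  arr <- round(vol$voxels)
  storage.mode(arr) <- "integer"
  arr <- aperm(arr, c(3L, 2L, 1L))  # (col, row, slice) -> NIfTI (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing[c(3, 2, 1)]
  RNifti::writeNifti(img, path)
  write_sidecar(paste0(path, ".json"), vol)
  invisible(path)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  jsonlite::read_json(path, simplifyVector = TRUE)
}

write_sidecar <- function(path, vol) {
  jsonlite::write_json(
    list(identifier = vol$identifier, origin = vol$origin,
         ctdi_vol_mgy = vol$ctdi_vol_mgy, spacing_mm = vol$spacing),
    path, auto_unbox = TRUE, digits = NA, na = "null")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
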