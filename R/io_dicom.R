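# Minimal CT DICOM series codec: Explicit VR Little Endian, MONOCHROME2,
# 16-bit single-frame slices, one file per slice. Covers exactly what the
# pipeline needs (geometry, rescale, series identity, pixel data); it is
# not a general DICOM implementation.

CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"

u16r <- function(x) as.raw(c(x %% 256L, x %/% 256L))
u32r <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dcm_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L) value <- c(value, pad)
  }
  stopifnot(is.raw(value))
  hdr <- c(u16r(group), u16r(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0L, 0L)), u32r(length(value)), value)
  } else {
    c(hdr, u16r(length(value)), value)
  }
}

dcm_us <- function(group, element, x)
  dcm_element(group, element, "US", u16r(as.integer(x)))

# deterministic UID derived from a label, so identical inputs give
# byte-identical files
dcm_uid <- function(label, suffix) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99999989
  paste0("2.25.", h, ".", suffix)
}

write_dicom_slice <- function(path, slice, spacing, z_mm, instance,
                              series_uid, study_uid, intercept = -1024,
                              slope = 1) {
  stored <- round((slice - intercept) / slope)
  if (any(stored < -32768 | stored > 32767))
    stop("stored pixel values exceed 16-bit signed range")
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2L,
                  endian = "little")

  sop_uid <- paste0(series_uid, ".", instance)
  meta <- c(
    dcm_element(2L, 1L, "OB", as.raw(c(0L, 1L))),
    dcm_element(2L, 2L, "UI", CT_SOP_CLASS),
    dcm_element(2L, 3L, "UI", sop_uid),
    dcm_element(2L, 16L, "UI", EXPLICIT_VR_LE)
  )
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", CT_SOP_CLASS),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0020, 0x000D, "UI", study_uid),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_element(0x0020, 0x0032, "DS",
                sprintf("0\\0\\%.6f", z_mm)),
    dcm_element(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_element(0x0018, 0x0050, "DS", sprintf("%.6f", spacing[1])),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, nrow(slice)),
    dcm_us(0x0028, 0x0011, ncol(slice)),
    dcm_element(0x0028, 0x0030, "DS",
                sprintf("%.6f\\%.6f", spacing[2], spacing[3])),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, 16L),
    dcm_us(0x0028, 0x0102, 15L),
    dcm_us(0x0028, 0x0103, 1L),
    dcm_element(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
    dcm_element(0x0028, 0x1053, "DS", sprintf("%g", slope)),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_element(2L, 0L, "UL", u32r(length(meta))), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

write_dicom_series <- function(vol, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vol$voxels)
  series_uid <- dcm_uid(vol$identifier, "1")
  study_uid <- dcm_uid(vol$identifier, "0")
  for (k in seq_len(d[1])) {
    write_dicom_slice(
      file.path(dir, sprintf("slice_%04d.dcm", k)),
      matrix(round(vol$voxels[k, , ]), d[2], d[3]),
      vol$spacing,
      z_mm = vol$origin[1] + (k - 1) * vol$spacing[1],
      instance = k, series_uid = series_uid, study_uid = study_uid)
  }
  write_sidecar(file.path(dir, "meta.json"), vol)
  invisible(dir)
}

# --- reading -----------------------------------------------------------

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  buf <- readBin(path, "raw", file.info(path)$size)
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  tags <- list()
  repeat {
    if (pos + 7L > length(buf)) break
    grp <- readBin(buf[pos:(pos + 1L)], "integer", size = 2L,
                   endian = "little", signed = FALSE)
    ele <- readBin(buf[(pos + 2L):(pos + 3L)], "integer", size = 2L,
                   endian = "little", signed = FALSE)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or unsupported encoding in ", path)
    if (vr %in% LONG_VRS) {
      len <- readBin(buf[(pos + 8L):(pos + 11L)], "integer", size = 4L,
                     endian = "little")
      vstart <- pos + 12L
    } else {
      len <- readBin(buf[(pos + 6L):(pos + 7L)], "integer", size = 2L,
                     endian = "little", signed = FALSE)
      vstart <- pos + 8L
    }
    value <- if (len > 0L) buf[vstart:(vstart + len - 1L)] else raw(0L)
    key <- sprintf("%04X,%04X", grp, ele)
    tags[[key]] <- list(vr = vr, value = value)
    pos <- vstart + len
    if (grp == 0x7FE0 && ele == 0x0010) break
  }
  tags
}

tag_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  v <- t$value[t$value != as.raw(0L)]  # drop UI null padding
  trimws(rawToChar(v))
}

tag_ds <- function(tags, key) {
  s <- tag_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

tag_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$value, "integer", size = 2L, endian = "little", signed = FALSE)
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .dcm files in ", dir)
  parsed <- lapply(files, parse_dicom_file)

  uids <- vapply(parsed, function(t) tag_str(t, "0020,000E") %||% "",
                 character(1))
  if (length(unique(uids)) != 1L)
    stop("mixed SeriesInstanceUID values in one directory: ",
         paste(unique(uids), collapse = ", "))

  slices <- lapply(parsed, function(tags) {
    slope <- tag_ds(tags, "0028,1053")
    inter <- tag_ds(tags, "0028,1052")
    if (is.null(slope)) stop("missing RescaleSlope (0028,1053)")
    if (is.null(inter)) stop("missing RescaleIntercept (0028,1052)")
    rows <- tag_us(tags, "0028,0010")
    cols <- tag_us(tags, "0028,0011")
    rep_ <- tag_us(tags, "0028,0103") %||% 1L
    pix <- tags[["7FE0,0010"]]
    if (is.null(pix)) stop("missing PixelData (7FE0,0010)")
    stored <- readBin(pix$value, "integer", n = rows * cols, size = 2L,
                      endian = "little", signed = (rep_ == 1L))
    hu <- t(matrix(stored, nrow = cols, ncol = rows)) * slope + inter
    ipp <- tag_ds(tags, "0020,0032")
    if (is.null(ipp)) stop("missing ImagePositionPatient (0020,0032)")
    list(hu = hu, z = ipp[3],
         pixel_spacing = tag_ds(tags, "0028,0030"),
         thickness = tag_ds(tags, "0018,0050"))
  })

  ord <- order(vapply(slices, `[[`, numeric(1), "z"))
  slices <- slices[ord]
  zs <- vapply(slices, `[[`, numeric(1), "z")
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(zs)
    if (any(abs(dz - dz[1]) > 0.01))
      stop("inconsistent slice spacing across the series (tolerance 0.01 mm)")
    slice_sp <- dz[1]
  } else {
    slice_sp <- slices[[1]]$thickness %||% 1
  }
  ps <- slices[[1]]$pixel_spacing
  if (is.null(ps)) stop("missing PixelSpacing (0028,0030)")

  arr <- array(0, c(nz, nrow(slices[[1]]$hu), ncol(slices[[1]]$hu)))
  for (k in seq_len(nz)) arr[k, , ] <- slices[[k]]$hu

  meta <- read_sidecar(file.path(dir, "meta.json"))
  ct_volume(arr, c(slice_sp, ps[1], ps[2]),
            origin = meta$origin %||% c(zs[1], 0, 0),
            ctdi_vol_mgy = meta$ctdi_vol_mgy %||% NA_real_,
            identifier = meta$identifier %||% basename(dir),
            clamp = TRUE)
}
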