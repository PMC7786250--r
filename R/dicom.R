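# Minimal DICOM I/O for uncompressed explicit-VR little-endian CT series.
# Covers only the tags a CT densitometry pipeline needs (geometry, rescale,
# 16-bit PixelData); anything else is skipped. Compressed transfer syntaxes
# and implicit VR are rejected with an explicit error.

EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"

# ---- parsing -------------------------------------------------------------

.u16 <- function(raw, at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                                  signed = FALSE, endian = "little")
.u32 <- function(raw, at) {
  v <- readBin(raw[at:(at + 3L)], "integer", size = 4, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# Parse one explicit-VR dataset starting at byte offset `at` (1-based);
# returns a named list tag -> raw value bytes.
parse_dicom_elements <- function(raw, at) {
  n <- length(raw)
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (at + 7L <= n) {
    group <- .u16(raw, at); elem <- .u16(raw, at + 2L)
    vr <- rawToChar(raw[(at + 4L):(at + 5L)])
    if (vr %in% long_vrs) {
      len <- .u32(raw, at + 8L)
      val_at <- at + 12L
    } else {
      len <- .u16(raw, at + 6L)
      val_at <- at + 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements unsupported")
    tag <- sprintf("%04x,%04x", group, elem)
    out[[tag]] <- if (len > 0) raw[val_at:(val_at + len - 1L)] else raw(0)
    at <- val_at + len
  }
  out
}

.dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  while (length(el) && el[length(el)] %in% as.raw(c(0x00, 0x20)))
    el <- el[-length(el)]
  rawToChar(el)
}
.dcm_ds <- function(el) if (is.null(el)) NULL else
  as.numeric(strsplit(.dcm_str(el), "\\\\")[[1]])
.dcm_us <- function(el) if (is.null(el)) NULL else
  readBin(el, "integer", size = 2, signed = FALSE, endian = "little")

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  els <- parse_dicom_elements(raw, 133L)
  ts <- .dcm_str(els[["0002,0010"]])
  if (!is.null(ts) && ts != EXPLICIT_VR_LE)
    stop("unsupported DICOM transfer syntax '", ts,
         "' (only uncompressed explicit VR little endian)")
  slope <- .dcm_ds(els[["0028,1053"]])
  intercept <- .dcm_ds(els[["0028,1052"]])
  if (is.null(slope) || is.null(intercept))
    stop("cannot convert to HU: RescaleSlope/RescaleIntercept missing in ", path)
  rows <- .dcm_us(els[["0028,0010"]]); cols <- .dcm_us(els[["0028,0011"]])
  bits <- .dcm_us(els[["0028,0100"]])
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns in ", path)
  if (!identical(bits, 16L)) stop("only 16-bit DICOM pixel data supported")
  signed <- identical(.dcm_us(els[["0028,0103"]]), 1L)
  px <- els[["7fe0,0010"]]
  if (is.null(px)) stop("missing PixelData in ", path)
  stored <- readBin(px, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
  if (!signed) stored[stored < 0] <- stored[stored < 0] + 65536
  hu <- matrix(stored * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE)
  list(hu = hu,
       pixel_spacing = .dcm_ds(els[["0028,0030"]]),
       slice_thickness = .dcm_ds(els[["0018,0050"]]),
       slice_location = .dcm_ds(els[["0020,1041"]]),
       instance_number = suppressWarnings(as.integer(.dcm_str(els[["0020,0013"]]))))
}

#' Read an uncompressed DICOM CT series as a volume
#'
#' Reads every `.dcm` file in `dir`, applies the rescale slope/intercept to
#' obtain Hounsfield units and stacks slices ordered by SliceLocation
#' (InstanceNumber when locations are absent).
#'
#' @param dir directory containing one series of single-frame `.dcm` files.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0) stop("no .dcm files in ", dir)
  slices <- lapply(files, read_dicom_file)
  loc <- vapply(slices, function(s)
    if (!is.null(s$slice_location)) s$slice_location else NA_real_, 0)
  ord <- if (all(is.finite(loc))) order(loc) else
    order(vapply(slices, function(s) s$instance_number %||% NA_integer_, 0L))
  slices <- slices[ord]
  dims <- vapply(slices, function(s) dim(s$hu), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions across the series")
  vox <- array(0, dim = c(length(slices), dims[1, 1], dims[2, 1]))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$hu
  ps <- slices[[1]]$pixel_spacing %||% c(1, 1)
  dz <- if (length(slices) > 1 && all(is.finite(loc)))
    abs(diff(sort(loc)))[1] else (slices[[1]]$slice_thickness %||% 1)
  ct_volume(vox, spacing = c(dz, ps[1], ps[2]))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# ---- writing (synthetic fixtures / export) -------------------------------

.pad_even <- function(x, pad = as.raw(0x20)) if (length(x) %% 2) c(x, pad) else x

.elem <- function(group, elem, vr, value_raw) {
  hdr <- writeBin(as.integer(c(group, elem)), raw(), size = 2, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(length(value_raw)), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(as.integer(length(value_raw)), raw(), size = 2, endian = "little"),
      value_raw)
  }
}
.elem_str <- function(group, elem, vr, s, pad = as.raw(0x20))
  .elem(group, elem, vr, .pad_even(charToRaw(s), pad))

#' Write a CT volume as a synthetic DICOM series
#'
#' Writes one uncompressed explicit-VR little-endian single-frame CT file
#' per slice, with HU encoded as 16-bit stored values under
#' RescaleSlope 1 / RescaleIntercept -1024. Intended for generating test
#' series and exchanging synthetic phantoms; it emits only the core image
#' module tags, not a complete patient-level DICOM header.
#'
#' @param volume a [ct_volume()]; HU values are rounded to integers.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(volume, dir) {
  stopifnot(is_ct_volume(volume))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  for (i in seq_len(d[1])) {
    stored <- round(volume$voxels[i, , ]) + 1024
    if (any(stored < 0) || any(stored > 65535))
      stop("HU out of encodable range for 16-bit storage")
    px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
    sop_uid <- sprintf("1.2.826.0.1.3680043.9999.1.%d", i)
    meta <- c(
      .elem_str(0x0002, 0x0002, "UI", CT_SOP_CLASS, as.raw(0)),
      .elem_str(0x0002, 0x0003, "UI", sop_uid, as.raw(0)),
      .elem_str(0x0002, 0x0010, "UI", EXPLICIT_VR_LE, as.raw(0))
    )
    meta <- c(.elem(0x0002, 0x0000, "UL",
                    writeBin(as.integer(length(meta)), raw(), size = 4,
                             endian = "little")), meta)
    body <- c(
      .elem_str(0x0008, 0x0016, "UI", CT_SOP_CLASS, as.raw(0)),
      .elem_str(0x0008, 0x0018, "UI", sop_uid, as.raw(0)),
      .elem_str(0x0008, 0x0060, "CS", "CT"),
      .elem_str(0x0018, 0x0050, "DS", format(volume$spacing[1])),
      .elem_str(0x0020, 0x0013, "IS", as.character(i)),
      .elem_str(0x0020, 0x1041, "DS",
                format(volume$origin[1] + (i - 1) * volume$spacing[1])),
      .elem(0x0028, 0x0002, "US", writeBin(1L, raw(), size = 2, endian = "little")),
      .elem_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .elem(0x0028, 0x0010, "US", writeBin(d[2], raw(), size = 2, endian = "little")),
      .elem(0x0028, 0x0011, "US", writeBin(d[3], raw(), size = 2, endian = "little")),
      .elem_str(0x0028, 0x0030, "DS",
                paste(format(volume$spacing[2:3]), collapse = "\\")),
      .elem(0x0028, 0x0100, "US", writeBin(16L, raw(), size = 2, endian = "little")),
      .elem(0x0028, 0x0101, "US", writeBin(16L, raw(), size = 2, endian = "little")),
      .elem(0x0028, 0x0102, "US", writeBin(15L, raw(), size = 2, endian = "little")),
      .elem(0x0028, 0x0103, "US", writeBin(0L, raw(), size = 2, endian = "little")),
      .elem_str(0x0028, 0x1052, "DS", "-1024"),
      .elem_str(0x0028, 0x1053, "DS", "1"),
      .elem(0x7fe0, 0x0010, "OW", px)
    )
    con <- file(file.path(dir, sprintf("slice%03d.dcm", i)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}
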