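#' CT volume in Hounsfield units
#'
#' A light container for a 3-D CT scan. Voxels are stored as a numeric
#' array in fixed `(slice, row, column)` axis order with per-axis physical
#' spacing in millimetres. All densitometry in the package operates on
#' these objects.
#'
#' @param voxels 3-D numeric array of Hounsfield units, axes
#'   `(slice, row, column)`.
#' @param spacing numeric length-3, physical voxel size in mm per axis;
#'   all entries must be positive.
#' @param origin numeric length-3, physical coordinate of voxel
#'   `(1, 1, 1)`; defaults to zeros.
#' @return An object of class `ct_volume` with elements `voxels`,
#'   `spacing` and `origin`.
#' @examples
#' vol <- ct_volume(array(33, dim = c(2, 8, 8)), spacing = c(5, 0.449, 0.449))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(1L, dim(voxels))
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3-D array")
  if (length(voxels) == 0L) stop("`voxels` must be non-empty")
  if (!all(is.finite(voxels))) stop("HU values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d slices of %d x %d, spacing %s mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

is_ct_volume <- function(x) inherits(x, "ct_volume")

#' Read a CT volume from disk
#'
#' Loads a NIfTI-1 file or an uncompressed DICOM series directory as a
#' [ct_volume()] in Hounsfield units. For DICOM, the per-file
#' RescaleSlope/RescaleIntercept are applied to the stored pixel values
#' and slices are ordered by SliceLocation (falling back to
#' InstanceNumber).
#'
#' @param path a `.nii`/`.nii.gz` file or a directory of `.dcm` files.
#' @param format `"auto"`, `"nifti"` or `"dicom"`.
#' @return A [ct_volume()].
#' @seealso [write_volume()]
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("cannot parse NIfTI file '", path,
                                             "': ", conditionMessage(e)))
    vox <- as.array(img)
    if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
    # NIfTI stores (x = column, y = row, z = slice); reorder to (slice, row, col)
    vox <- aperm(vox, c(3, 2, 1))
    pd <- RNifti::pixdim(img)
    ct_volume(vox, spacing = rev(pd[seq_len(3)]))
  } else {
    read_dicom_series(path)
  }
}

#' Write a CT volume to a NIfTI-1 file
#'
#' @param volume a [ct_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype passed to [RNifti::writeNifti()]; the default `"double"`
#'   round-trips float HU within 1e-6 and integer HU exactly.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  stopifnot(is_ct_volume(volume))
  arr <- aperm(volume$voxels, c(3, 2, 1))   # back to NIfTI (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
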