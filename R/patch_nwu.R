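# Mirrored-patch densitometry. A patch pair is two size x size windows on
# the same axial slice, reflected across the midsagittal (column-midline)
# plane; the hypoattenuated member is the ischemic patch. The patch-based
# net water uptake is
#
#     NWU = 1 - D_ischemic / D_normal
#
# with D_* the mean HU of the ischemic / contralateral normal tissue.

#' Patch placement specification
#'
#' Indices are 0-based (slice, row, column), matching how placements are
#' exchanged in CSV/JSON; the patch covers the half-open window
#' `[center - size/2, center + size/2)` in each in-plane axis.
#'
#' @param slice 0-based slice index.
#' @param center_row,center_col 0-based centre voxel coordinates.
#' @param size patch edge length in voxels; even and >= 2 (default 30).
#' @return A `patch_spec` list.
#' @export
patch_spec <- function(slice, center_row, center_col, size = 30L) {
  size <- as.integer(size)
  if (size < 2L || size %% 2L != 0L) stop("`size` must be even and >= 2")
  structure(list(slice = as.integer(slice),
                 center_row = as.integer(center_row),
                 center_col = as.integer(center_col), size = size),
            class = "patch_spec")
}

patch_window <- function(center, size) {
  h <- size %/% 2L
  c(center - h, center + h - 1L)   # inclusive 0-based bounds
}

check_patch_in_volume <- function(spec, volume_shape, what = "patch") {
  d <- volume_shape
  if (spec$slice < 0 || spec$slice >= d[1])
    stop(what, " slice ", spec$slice, " outside volume (", d[1], " slices)")
  rw <- patch_window(spec$center_row, spec$size)
  cw <- patch_window(spec$center_col, spec$size)
  if (rw[1] < 0 || rw[2] >= d[2] || cw[1] < 0 || cw[2] >= d[3])
    stop(what, " extent rows [", rw[1], ",", rw[2], "] cols [", cw[1], ",",
         cw[2], "] falls outside the ", d[2], " x ", d[3], " slice")
  invisible(spec)
}

#' Reflect a patch centre across the midsagittal plane
#'
#' The mirrored placement keeps the slice and row and maps the column to
#' `(n_cols - 1) - col`; applying it twice returns the original spec.
#'
#' @param spec a [patch_spec()].
#' @param volume_shape integer length-3 `(slices, rows, cols)`.
#' @return The mirrored [patch_spec()].
#' @export
mirror_center <- function(spec, volume_shape) {
  check_patch_in_volume(spec, volume_shape)
  m <- patch_spec(spec$slice, spec$center_row,
                  (volume_shape[3] - 1L) - spec$center_col, spec$size)
  check_patch_in_volume(m, volume_shape, what = "mirrored patch")
  m
}

#' Extract a patch of HU values
#'
#' @param volume a [ct_volume()].
#' @param spec a [patch_spec()].
#' @return `size x size` numeric matrix of HU values.
#' @export
extract_patch <- function(volume, spec) {
  stopifnot(is_ct_volume(volume), inherits(spec, "patch_spec"))
  check_patch_in_volume(spec, dim(volume$voxels))
  rw <- patch_window(spec$center_row, spec$size)
  cw <- patch_window(spec$center_col, spec$size)
  volume$voxels[spec$slice + 1L, (rw[1]:rw[2]) + 1L, (cw[1]:cw[2]) + 1L]
}

#' Screen a patch for CSF and bone contamination
#'
#' Low-HU cerebrospinal fluid inside a patch deflates the measured density
#' and so inflates NWU; placements are expected to avoid CSF spaces. The
#' report flags a patch whose CSF voxel fraction exceeds
#' `max_csf_fraction`, and likewise counts bone-bright voxels.
#'
#' @param patch numeric matrix of HU values.
#' @param csf_hu_threshold voxels below this HU count as CSF (default 20).
#' @param max_csf_fraction largest acceptable CSF fraction (default 0.1).
#' @param bone_hu_threshold voxels above this HU count as bone (default 100).
#' @return List: `valid`, `csf_fraction`, `csf_count`, `bone_fraction`,
#'   `bone_count`, `n_voxels`.
#' @export
validate_patch <- function(patch, csf_hu_threshold = 20,
                           max_csf_fraction = 0.1,
                           bone_hu_threshold = 100) {
  n <- length(patch)
  csf <- sum(patch < csf_hu_threshold)
  bone <- sum(patch > bone_hu_threshold)
  list(valid = (csf / n) <= max_csf_fraction && (bone / n) <= max_csf_fraction,
       csf_fraction = csf / n, csf_count = csf,
       bone_fraction = bone / n, bone_count = bone, n_voxels = n)
}

#' Classify a mirrored pair into ischemic and normal patches
#'
#' The member with the strictly lower mean HU (hypoattenuation) is
#' ischemic. When the means are equal to within `tol`, `declared_side`
#' breaks the tie; with no declared side an ambiguity error is raised.
#'
#' @param left_patch,right_patch HU matrices of identical shape; "left" and
#'   "right" refer to the column direction of the volume.
#' @param declared_side optional `"left"` or `"right"`: the side known (or
#'   believed) to carry the lesion, used only to break ties.
#' @param tol equality tolerance on the means.
#' @return A `patch_pair`: `ischemic`, `normal` (matrices),
#'   `ischemic_side`, `d_ischemic`, `d_normal`.
#' @export
classify_pair <- function(left_patch, right_patch, declared_side = NULL,
                          tol = 1e-9) {
  if (!identical(dim(left_patch), dim(right_patch)))
    stop("patches must have the same shape")
  ml <- mean(left_patch); mr <- mean(right_patch)
  side <- if (abs(ml - mr) <= tol) {
    if (is.null(declared_side))
      stop("ambiguous pair: equal mean HU and no declared side")
    match.arg(declared_side, c("left", "right"))
  } else if (ml < mr) "left" else "right"
  isch <- if (side == "left") left_patch else right_patch
  norm <- if (side == "left") right_patch else left_patch
  structure(list(ischemic = isch, normal = norm, ischemic_side = side,
                 d_ischemic = mean(isch), d_normal = mean(norm)),
            class = "patch_pair")
}

#' Patch-based net water uptake from classified pairs
#'
#' Applies `NWU = 1 - D_ischemic / D_normal`. In `"pooled"` mode (default)
#' the densities are voxel-weighted means over all ischemic / all normal
#' patches, treating the pooled patches as one ischemic core; `"per_pair"`
#' averages the per-pair NWU values instead. Both are returned.
#'
#' @param pairs list of `patch_pair` objects (typically four); at least one.
#' @param pooling `"pooled"` or `"per_pair"`.
#' @return An `nwu_result`: `ip_nwu` (per the chosen pooling), `pooled`,
#'   `per_pair_mean`, `per_pair_nwu`, `pooling`.
#' @export
compute_ip_nwu <- function(pairs, pooling = c("pooled", "per_pair")) {
  pooling <- match.arg(pooling)
  if (inherits(pairs, "patch_pair")) pairs <- list(pairs)
  if (length(pairs) < 1) stop("need at least one patch pair")
  stopifnot(all(vapply(pairs, inherits, TRUE, "patch_pair")))
  dn <- vapply(pairs, `[[`, 0, "d_normal")
  if (any(dn <= 0))
    stop("non-physical parenchyma: normal-patch mean HU <= 0")
  di <- vapply(pairs, `[[`, 0, "d_ischemic")
  nvox <- vapply(pairs, function(p) length(p$ischemic), 0)
  pooled <- 1 - (sum(di * nvox) / sum(nvox)) / (sum(dn * nvox) / sum(nvox))
  per_pair <- 1 - di / dn
  structure(list(ip_nwu = if (pooling == "pooled") pooled else mean(per_pair),
                 pooled = pooled, per_pair_mean = mean(per_pair),
                 per_pair_nwu = per_pair, pooling = pooling),
            class = "nwu_result")
}

#' @export
print.nwu_result <- function(x, ...) {
  cat(sprintf("<nwu_result> NWU = %.4f (%s; per-pair: %s)\n", x$ip_nwu,
              x$pooling, paste(sprintf("%.3f", x$per_pair_nwu), collapse = ", ")))
  invisible(x)
}

#' Voxel-wise NWU ratio maps from classified pairs
#'
#' Element `(i, j)` of each map is `1 - ischemic(i,j) / normal(i,j)`
#' (voxel against its mirrored voxel), clamped into `[0, 1]`; voxels whose
#' mirrored (normal) value is <= 1 HU have no meaningful ratio and are
#' excluded (NA) and counted. With `map_value = "ratio"` the raw ratio
#' `ischemic / normal` is stored instead, clamped the same way.
#'
#' @param pairs list of `patch_pair` objects.
#' @param map_value `"nwu"` (default) or `"ratio"`.
#' @param min_normal_hu exclusion threshold on the normal voxel (default 1).
#' @return A `ratio_map_set`: `maps` (list of matrices), `clamp_count`,
#'   `excluded_count`, `n_retained`, `map_value`.
#' @export
compute_ratio_maps <- function(pairs, map_value = c("nwu", "ratio"),
                               min_normal_hu = 1) {
  map_value <- match.arg(map_value)
  if (inherits(pairs, "patch_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) >= 1,
            all(vapply(pairs, inherits, TRUE, "patch_pair")))
  clamped <- 0L; excluded <- 0L
  maps <- lapply(pairs, function(p) {
    bad <- p$normal <= min_normal_hu
    v <- if (map_value == "nwu") 1 - p$ischemic / p$normal
         else p$ischemic / p$normal
    out_of_range <- !bad & (v < 0 | v > 1)
    clamped <<- clamped + sum(out_of_range)
    excluded <<- excluded + sum(bad)
    v <- pmin(pmax(v, 0), 1)
    v[bad] <- NA_real_
    v
  })
  n_ret <- sum(vapply(maps, function(m) sum(!is.na(m)), 0))
  if (n_ret == 0) stop("all voxels excluded: no valid mirrored ratios")
  structure(list(maps = maps, clamp_count = clamped,
                 excluded_count = excluded, n_retained = n_ret,
                 map_value = map_value),
            class = "ratio_map_set")
}

#' One-call patch NWU measurement on a volume
#'
#' For each placement, mirrors the centre across the midline, extracts both
#' patches, classifies the pair (optionally informed by the known lesion
#' side), and returns the NWU result together with the pairs, voxel-wise
#' ratio maps and per-patch validity reports.
#'
#' @param volume a [ct_volume()].
#' @param specs list of [patch_spec()] placements (either side; the mirror
#'   is derived).
#' @param declared_side optional `"left"`/`"right"` tie-break lesion side.
#' @param pooling passed to [compute_ip_nwu()].
#' @return List: `nwu` (`nwu_result`), `pairs`, `ratio_maps`, `validity`.
#' @export
measure_ip_nwu <- function(volume, specs, declared_side = NULL,
                           pooling = "pooled") {
  if (inherits(specs, "patch_spec")) specs <- list(specs)
  d <- dim(volume$voxels)
  pairs <- lapply(specs, function(sp) {
    msp <- mirror_center(sp, d)
    a <- extract_patch(volume, sp); b <- extract_patch(volume, msp)
    if (sp$center_col <= msp$center_col)
      classify_pair(a, b, declared_side) else classify_pair(b, a, declared_side)
  })
  validity <- lapply(pairs, function(p)
    list(ischemic = validate_patch(p$ischemic), normal = validate_patch(p$normal)))
  list(nwu = compute_ip_nwu(pairs, pooling = pooling), pairs = pairs,
       ratio_maps = compute_ratio_maps(pairs), validity = validity)
}
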