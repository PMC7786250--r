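# Segmented-region NWU: align admission and follow-up scans to a common
# symmetric template grid, overlay the follow-up lesion segmentation on the
# admission image, mirror it across the midsagittal plane, and apply
# NWU = 1 - D_ischemic / D_normal to the two mean densities.
#
# Physical coordinates are voxel indices centred on the grid and scaled by
# spacing; a transform maps source (moving) physical coordinates to
# template (fixed) ones, and resampling pulls through its inverse.

#' 12-parameter affine transform
#'
#' Either supply the `linear` 3x3 matrix directly, or build it from
#' rotation / scale / shear parameters. Coordinates are physical (mm),
#' centred on the grid; `direction` is source-to-template.
#'
#' @param translation length-3 translation in mm.
#' @param rotation_deg length-3 rotation angles (degrees) about the slice,
#'   row and column axes (a scalar rotates in-plane, i.e. about the slice
#'   axis).
#' @param scale scalar or length-3 scale factors.
#' @param shear length-3 shear coefficients.
#' @param linear optional explicit 3x3 linear part (overrides the above).
#' @return An `affine_transform12` with invertible `linear` and
#'   `translation`.
#' @export
affine_transform <- function(translation = c(0, 0, 0), rotation_deg = 0,
                             scale = 1, shear = c(0, 0, 0), linear = NULL) {
  if (is.null(linear)) {
    ang <- rep(rotation_deg, length.out = 3) * pi / 180
    if (length(rotation_deg) == 1) ang <- c(rotation_deg * pi / 180, 0, 0)
    rot1 <- matrix(c(1, 0, 0,
                     0, cos(ang[1]), -sin(ang[1]),
                     0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
    rot2 <- matrix(c(cos(ang[2]), 0, sin(ang[2]),
                     0, 1, 0,
                     -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
    rot3 <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                     sin(ang[3]), cos(ang[3]), 0,
                     0, 0, 1), 3, byrow = TRUE)
    sc <- diag(rep(scale, length.out = 3))
    sh <- diag(3); sh[1, 2] <- shear[1]; sh[1, 3] <- shear[2]; sh[2, 3] <- shear[3]
    linear <- rot1 %*% rot2 %*% rot3 %*% sc %*% sh
  }
  linear <- matrix(as.numeric(linear), 3, 3)
  if (abs(det(linear)) < 1e-12) stop("linear part is singular")
  structure(list(linear = linear, translation = as.numeric(translation),
                 direction = "source_to_template"),
            class = "affine_transform12")
}

#' Serialize / deserialize a transform as 12 numbers
#'
#' Row-major linear part followed by the translation, the JSON exchange
#' format for transforms.
#' @param transform an [affine_transform()].
#' @param x numeric length-12 (or JSON file path for `read_transform`).
#' @param path output JSON path.
#' @return `transform_params` returns numeric length-12.
#' @export
transform_params <- function(transform)
  c(as.numeric(t(transform$linear)), transform$translation)

#' @rdname transform_params
#' @export
write_transform <- function(transform, path)
  jsonlite::write_json(transform_params(transform), path, digits = NA)

#' @rdname transform_params
#' @export
read_transform <- function(x) {
  if (is.character(x)) x <- as.numeric(unlist(jsonlite::read_json(x)))
  stopifnot(length(x) == 12)
  affine_transform(linear = matrix(x[1:9], 3, byrow = TRUE),
                   translation = x[10:12])
}

# centred physical coordinates of every voxel: n x 3 matrix, axis order
# (slice, row, col)
grid_phys_coords <- function(shape, spacing) {
  half <- (shape - 1) / 2
  s <- (seq_len(shape[1]) - 1 - half[1]) * spacing[1]
  r <- (seq_len(shape[2]) - 1 - half[2]) * spacing[2]
  cc <- (seq_len(shape[3]) - 1 - half[3]) * spacing[3]
  cbind(rep(s, times = shape[2] * shape[3]),
        rep(rep(r, each = shape[1]), times = shape[3]),
        rep(cc, each = shape[1] * shape[2]))
}

# trilinear / nearest sampling of `arr` at continuous 0-based voxel coords
sample_volume <- function(arr, vox, method = "linear", fill = NA_real_) {
  d <- dim(arr)
  valid <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  out <- rep(fill, nrow(vox))
  if (!any(valid)) return(list(values = out, valid = valid))
  v <- vox[valid, , drop = FALSE]
  if (method == "nearest") {
    idx <- round(v)
    lin <- 1 + idx[, 1] + idx[, 2] * d[1] + idx[, 3] * d[1] * d[2]
    out[valid] <- arr[lin]
  } else {
    f <- pmin(floor(v), rep(d, each = nrow(v)) - 2)
    f <- pmax(f, 0)
    t <- v - f
    acc <- numeric(nrow(v))
    for (ds in 0:1) for (dr in 0:1) for (dc in 0:1) {
      w <- (if (ds) t[, 1] else 1 - t[, 1]) *
        (if (dr) t[, 2] else 1 - t[, 2]) *
        (if (dc) t[, 3] else 1 - t[, 3])
      lin <- 1 + (f[, 1] + ds) + (f[, 2] + dr) * d[1] +
        (f[, 3] + dc) * d[1] * d[2]
      acc <- acc + w * arr[lin]
    }
    out[valid] <- acc
  }
  list(values = out, valid = valid)
}

# separable 1-2-1 in-plane blur; suppresses aliasing of thin structures
# (the one-voxel skull ring at coarse pyramid levels) that would otherwise
# put local bumps in the similarity metric
blur_inplane <- function(volume, passes = 1) {
  v <- volume$voxels
  for (k in seq_len(passes)) {
    n2 <- dim(v)[2]; n3 <- dim(v)[3]
    v <- (v[, c(1, 1:(n2 - 1)), , drop = FALSE] + 2 * v +
            v[, c(2:n2, n2), , drop = FALSE]) / 4
    v <- (v[, , c(1, 1:(n3 - 1)), drop = FALSE] + 2 * v +
            v[, , c(2:n3, n3), drop = FALSE]) / 4
  }
  volume$voxels <- v
  volume
}

# block-mean downsample of rows/cols by integer factor (slices untouched)
downsample_inplane <- function(volume, factor) {
  if (factor == 1) return(volume)
  d <- dim(volume$voxels)
  nr <- d[2] %/% factor; nc <- d[3] %/% factor
  v <- volume$voxels[, seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  a <- array(v, dim = c(d[1], factor, nr, factor, nc))
  small <- apply(a, c(1, 3, 5), mean)
  ct_volume(small, spacing = volume$spacing * c(1, factor, factor))
}

registration_metric <- function(fv, mv, metric) {
  if (metric == "ncc") {
    if (stats::sd(fv) == 0 || stats::sd(mv) == 0) return(0)
    stats::cor(fv, mv)
  } else {   # mutual information, 32-bin partial-volume joint histogram
    nb <- 32
    soft_bin <- function(x) {
      r <- range(x)
      b <- (x - r[1]) / max(r[2] - r[1], 1e-12) * (nb - 1)
      f <- pmin(floor(b), nb - 2)
      list(lo = f + 1, frac = b - f)
    }
    bx <- soft_bin(fv); by <- soft_bin(mv)
    jt <- matrix(0, nb, nb)
    for (dx in 0:1) for (dy in 0:1) {
      w <- (if (dx) bx$frac else 1 - bx$frac) *
        (if (dy) by$frac else 1 - by$frac)
      k <- (bx$lo + dx) + nb * (by$lo + dy - 1)
      s <- rowsum(w, k)
      jt[as.integer(rownames(s))] <- jt[as.integer(rownames(s))] + s
    }
    jt <- jt / sum(jt)
    px <- rowSums(jt); py <- colSums(jt)
    hx <- -sum(px[px > 0] * log(px[px > 0]))
    hy <- -sum(py[py > 0] * log(py[py > 0]))
    hxy <- -sum(jt[jt > 0] * log(jt[jt > 0]))
    hx + hy - hxy
  }
}

params_to_transform <- function(p)
  affine_transform(translation = p[1:3], rotation_deg = p[4:6] * 180 / pi,
                   scale = exp(p[7:9]), shear = p[10:12])

#' Estimate a 12-degree-of-freedom affine alignment
#'
#' Registers `moving` to `fixed` by maximizing an intensity-similarity
#' metric over translation, rotation, anisotropic scale and shear, using a
#' coarse-to-fine in-plane pyramid and derivative-free (Nelder-Mead)
#' optimization. Fully deterministic: the search always starts from the
#' identity.
#'
#' @param moving,fixed [ct_volume()] objects with overlapping fields of
#'   view.
#' @param metric `"ncc"` (normalized cross-correlation, default for
#'   same-modality CT) or `"mi"` (mutual information).
#' @param pyramid integer in-plane downsampling factors, coarse to fine.
#' @param maxit quasi-Newton iteration budget per stage.
#' @return An [affine_transform()] mapping moving physical coordinates to
#'   fixed ones, with attributes `metric_value` and `convergence`.
#' @export
register_affine <- function(moving, fixed, metric = c("ncc", "mi"),
                            pyramid = c(4, 2), maxit = 60) {
  metric <- match.arg(metric)
  stopifnot(is_ct_volume(moving), is_ct_volume(fixed))
  obj_for <- function(fx, mv) {
    d <- dim(fx$voxels)
    phys <- grid_phys_coords(d, fx$spacing)
    fvals <- as.numeric(fx$voxels)
    mhalf <- (dim(mv$voxels) - 1) / 2
    ext <- max(d * fx$spacing)
    function(p) {
      # soft bounds keep the quasi-Newton line search out of the
      # singular/degenerate corner of parameter space
      if (any(abs(p[1:3]) > ext) || any(abs(p[4:12]) > 0.7)) return(10)
      tr <- params_to_transform(p)
      src <- t(solve(tr$linear, t(phys) - tr$translation))
      vox <- sweep(src, 2, mv$spacing, "/")
      vox <- sweep(vox, 2, mhalf, "+")
      s <- sample_volume(mv$voxels, vox, "linear")
      if (mean(s$valid) < 0.25) return(10)
      -registration_metric(fvals[s$valid], s$values[s$valid], metric)
    }
  }
  p <- rep(0, 12)
  pscale <- c(rep(2, 3), rep(0.05, 9))
  conv <- NA_integer_
  stage <- function(p, ob, free, iter) {
    fn <- function(q) { pp <- p; pp[free] <- q; ob(pp) }
    res <- stats::optim(p[free], fn, method = "BFGS",
                        control = list(maxit = iter, parscale = pscale[free],
                                       ndeps = rep(1e-2, length(free)),
                                       reltol = 1e-10))
    conv <<- res$convergence
    p[free] <- res$par
    p
  }
  for (k in seq_along(pyramid)) {
    passes <- if (k == 1) 2 else 1
    fx <- blur_inplane(downsample_inplane(fixed, pyramid[k]), passes)
    mv <- blur_inplane(downsample_inplane(moving, pyramid[k]), passes)
    ob <- obj_for(fx, mv)
    if (k == 1) {             # widen the basin: translation, then rigid+scale
      p <- stage(p, ob, 1:3, maxit)
      p <- stage(p, ob, 1:9, maxit)
    }
    p <- stage(p, ob, 1:12, if (k == length(pyramid)) maxit %/% 2 else maxit)
  }
  final <- -obj_for(fixed, moving)(p)
  if (metric == "ncc" && final < 0.2)
    stop(sprintf(paste0("registration failed to converge: final correlation ",
                        "%.3f (params: %s)"), final,
                 paste(signif(p, 3), collapse = ", ")))
  tr <- params_to_transform(p)
  attr(tr, "metric_value") <- final
  attr(tr, "convergence") <- conv
  tr
}

#' Resample a volume or mask through an affine transform
#'
#' Pulls `x` onto the grid of `target_grid` through the inverse of
#' `transform` (which maps `x`-space to target space). HU volumes use
#' trilinear interpolation; masks use nearest-neighbour so labels stay
#' binary. Out-of-field voxels receive `fill` and are counted in the
#' `oof_count` attribute.
#'
#' @param x a [ct_volume()] or a logical/0-1 array mask.
#' @param transform an [affine_transform()]; defaults to identity.
#' @param target_grid a [ct_volume()] (its shape/spacing define the grid)
#'   or a list with `shape` and `spacing`.
#' @param interpolation `"auto"` (linear for volumes, nearest for masks),
#'   `"linear"` or `"nearest"`.
#' @param fill value for voxels mapping outside `x` (default -1000 for
#'   volumes, 0 for masks).
#' @return Same type as `x`, on the target grid.
#' @export
resample_to <- function(x, transform = affine_transform(), target_grid,
                        interpolation = c("auto", "linear", "nearest"),
                        fill = NULL) {
  interpolation <- match.arg(interpolation)
  is_vol <- is_ct_volume(x)
  if (interpolation == "auto")
    interpolation <- if (is_vol) "linear" else "nearest"
  if (is.null(fill)) fill <- if (is_vol) -1000 else 0
  arr <- if (is_vol) x$voxels else (x != 0) * 1
  sp_src <- if (is_vol) x$spacing else attr(x, "spacing") %||% c(1, 1, 1)
  tg_shape <- if (is_ct_volume(target_grid)) dim(target_grid$voxels)
              else target_grid$shape
  tg_spacing <- if (is_ct_volume(target_grid)) target_grid$spacing
                else target_grid$spacing
  phys <- grid_phys_coords(tg_shape, tg_spacing)
  src <- t(solve(transform$linear, t(phys) - transform$translation))
  vox <- sweep(src, 2, sp_src, "/")
  vox <- sweep(vox, 2, (dim(arr) - 1) / 2, "+")
  s <- sample_volume(arr, vox, interpolation, fill = fill)
  if (!any(s$valid)) stop("empty overlap: no target voxel maps inside the source")
  out <- array(s$values, dim = tg_shape)
  if (is_vol) {
    res <- ct_volume(out, spacing = tg_spacing, origin = x$origin)
    attr(res, "oof_count") <- sum(!s$valid)
    res
  } else {
    res <- array(out != 0, dim = tg_shape)
    attr(res, "oof_count") <- sum(!s$valid)
    res
  }
}

#' Mirror a lesion mask across the midsagittal plane
#'
#' Reflects the mask in the column direction of a symmetric (template)
#' grid: column `j` maps to `n_cols - 1 - j` (0-based). Voxel count is
#' conserved and the operation is an involution.
#'
#' @param mask logical/0-1 3-D array.
#' @return Logical array of the same shape.
#' @export
mirror_mask <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  out <- (mask != 0)[, , d[3]:1, drop = FALSE]
  dim(out) <- d
  out
}

#' Segmented-region net water uptake
#'
#' `D_ischemic` is the mean admission HU under the lesion mask and
#' `D_normal` the mean under its midline mirror; `NWU = 1 - D_I / D_N`.
#' Voxel pairs where either member falls outside the parenchymal HU window
#' are excluded symmetrically (suppressing CSF/bone contamination) and
#' counted.
#'
#' @param admission a [ct_volume()] in (symmetric) template space.
#' @param lesion_mask logical 3-D array on the same grid, >= 1 voxel.
#' @param hu_window length-2 parenchymal HU window (default `c(5, 100)`).
#' @return List of class `sr_nwu_result`: `sr_nwu`, `d_ischemic`,
#'   `d_normal`, `n_used`, `excluded_count`.
#' @export
compute_sr_nwu <- function(admission, lesion_mask, hu_window = c(5, 100)) {
  stopifnot(is_ct_volume(admission))
  if (!identical(dim(admission$voxels), dim(lesion_mask)))
    stop("admission volume and lesion mask must share one grid")
  les <- lesion_mask != 0
  if (sum(les) < 1) stop("lesion mask is empty")
  hu_les <- admission$voxels[les]
  hu_mir <- admission$voxels[, , dim(les)[3]:1, drop = FALSE][les]
  keep <- hu_les >= hu_window[1] & hu_les <= hu_window[2] &
    hu_mir >= hu_window[1] & hu_mir <= hu_window[2]
  if (!any(keep)) stop("all mask voxels excluded by the HU window")
  d_i <- mean(hu_les[keep]); d_n <- mean(hu_mir[keep])
  if (d_n <= 0) stop("non-physical parenchyma: mirrored-region mean HU <= 0")
  structure(list(sr_nwu = 1 - d_i / d_n, d_ischemic = d_i, d_normal = d_n,
                 n_used = sum(keep), excluded_count = sum(!keep)),
            class = "sr_nwu_result")
}

#' Synthetic symmetric head template
#'
#' A noise-free, lesion-free, exactly midline-symmetric head phantom usable
#' as the common registration target when no standard-space template volume
#' is available. Synthetic: it shares the geometry of [generate_phantom()],
#' not any real atlas anatomy.
#'
#' @param image_shape,spacing grid definition, as in [phantom_spec()].
#' @return A [ct_volume()].
#' @export
synthetic_template <- function(image_shape = c(8, 160, 160),
                               spacing = c(5, 0.449, 0.449)) {
  generate_phantom(phantom_spec(image_shape = image_shape,
                                water_uptake_w = 0, noise_sigma = 0,
                                spacing = spacing))$volume
}
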