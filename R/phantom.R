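# Synthetic head-CT phantom: a bilaterally symmetric "head" (elliptical
# skull ring, parenchyma, two paramedian CSF ventricles) plus a unilateral
# MCA-territory lesion in which HU = parenchyma_hu * (1 - w) before noise.
# The multiplicative attenuation model is exactly the physics behind
# NWU = 1 - D_ischemic / D_normal, so the generator carries a known ground
# truth against which both patch-based and region-based estimates can be
# checked.

#' Specification of a synthetic head phantom
#'
#' @param image_shape integer length-3 voxel counts `(slices, rows, cols)`;
#'   at least 4 slices and 64 x 64 in-plane so a 30 x 30 patch fits in the
#'   lesion.
#' @param parenchyma_hu,csf_hu,skull_hu,background_hu tissue densities in
#'   HU; must satisfy `csf_hu < parenchyma_hu < skull_hu`.
#' @param lesion_side `"left"` or `"right"` (column direction).
#' @param water_uptake_w true fractional water uptake in `[0, 1)`; lesion
#'   voxels get `parenchyma_hu * (1 - w)` before noise.
#' @param noise_sigma SD of additive i.i.d. Gaussian noise in HU.
#' @param w_heterogeneity SD of a smooth zero-mean spatial field added to
#'   `w` inside the lesion (0 = spatially uniform uptake). Emulates the
#'   core-to-rim heterogeneity of real edema; zero-mean within the lesion,
#'   so the mean uptake is unchanged.
#' @param misalignment optional list with any of `translation` (length-3
#'   voxels), `rotation_deg` (in-plane) and `scale`; the generated head is
#'   resampled through the corresponding affine, for registration testing.
#' @param spacing physical voxel size in mm, default matching a typical
#'   axial head protocol (5 mm slices, 0.449 mm in-plane).
#' @param seed RNG seed making generation reproducible; `NULL` uses the
#'   current RNG state.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_shape = c(8, 160, 160),
                         parenchyma_hu = 33, csf_hu = 5, skull_hu = 700,
                         background_hu = -1000,
                         lesion_side = c("right", "left"),
                         water_uptake_w = 0.2,
                         noise_sigma = 2,
                         w_heterogeneity = 0,
                         misalignment = NULL,
                         spacing = c(5, 0.449, 0.449),
                         seed = NULL) {
  lesion_side <- match.arg(lesion_side)
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 3, all(image_shape >= c(4, 64, 64)))
  if (!(csf_hu < parenchyma_hu && parenchyma_hu < skull_hu))
    stop("need csf_hu < parenchyma_hu < skull_hu")
  if (water_uptake_w < 0 || water_uptake_w >= 1)
    stop("water_uptake_w must be in [0, 1)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (w_heterogeneity < 0) stop("w_heterogeneity must be >= 0")
  structure(as.list(environment()), class = "phantom_spec")
}

# In-plane geometry in 0-based voxel coordinates; all centres are placed
# symmetrically about the column midline (nc-1)/2 so that a w = 0 noise-free
# phantom is exactly mirror-symmetric.
phantom_geometry <- function(image_shape, lesion_side) {
  ns <- image_shape[1]; nr <- image_shape[2]; nc <- image_shape[3]
  mr <- (nr - 1) / 2; mc <- (nc - 1) / 2
  side_sign <- if (lesion_side == "right") 1 else -1
  lo <- floor(ns / 4); hi <- ceiling(3 * ns / 4) - 1   # central half, 0-based
  list(
    mr = mr, mc = mc,
    brain_semi = c(0.44 * nr, 0.41 * nc),
    skull_semi = c(0.48 * nr, 0.45 * nc),
    vent_centers = list(c(mr, mc - 0.05 * nc), c(mr, mc + 0.05 * nc)),
    vent_semi = c(0.10 * nr, 0.022 * nc),
    lesion_center = c(mr, mc + side_sign * 0.228 * nc),
    lesion_semi = c(0.19 * nr, 0.15 * nc),
    lesion_slices = (lo:hi) + 1L   # 1-based slice indices
  )
}

inside_ellipse <- function(rowg, colg, center, semi)
  ((rowg - center[1]) / semi[1])^2 + ((colg - center[2]) / semi[2])^2 < 1

# Smooth zero-mean unit-SD field over an (nr, nc) slice: coarse white noise
# bilinearly upsampled (correlation length ~ `step` voxels).
smooth_field <- function(nr, nc, step = 6) {
  gr <- seq(0, nr - 1, by = step); gc <- seq(0, nc - 1, by = step)
  if (gr[length(gr)] < nr - 1) gr <- c(gr, nr - 1)
  if (gc[length(gc)] < nc - 1) gc <- c(gc, nc - 1)
  coarse <- matrix(stats::rnorm(length(gr) * length(gc)), length(gr))
  ri <- findInterval(0:(nr - 1), gr, rightmost.closed = TRUE)
  ci <- findInterval(0:(nc - 1), gc, rightmost.closed = TRUE)
  rf <- (0:(nr - 1) - gr[ri]) / pmax(gr[pmin(ri + 1, length(gr))] - gr[ri], 1)
  cf <- (0:(nc - 1) - gc[ci]) / pmax(gc[pmin(ci + 1, length(gc))] - gc[ci], 1)
  r2 <- pmin(ri + 1, length(gr)); c2 <- pmin(ci + 1, length(gc))
  out <- outer(1 - rf, 1 - cf) * coarse[ri, ci] +
    outer(rf, 1 - cf) * coarse[r2, ci] +
    outer(1 - rf, cf) * coarse[ri, c2] +
    outer(rf, cf) * coarse[r2, c2]
  out
}

#' Generate a synthetic head phantom with known water uptake
#'
#' Builds the symmetric head described by [phantom_spec()] and inserts a
#' lesion whose pre-noise HU equals `parenchyma_hu * (1 - w)`; returns the
#' volume together with the exact lesion mask and the true uptake, the
#' ground truth for every NWU estimator in the package.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `ct_phantom`: `volume` ([ct_volume()]),
#'   `lesion_mask` (logical array, same shape), `true_w`, `lesion_side`,
#'   and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(water_uptake_w = 0.2, noise_sigma = 0))
#' mean(ph$volume$voxels[ph$lesion_mask]) / 33   # = 1 - 0.2
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ns <- spec$image_shape[1]; nr <- spec$image_shape[2]; nc <- spec$image_shape[3]
  g <- phantom_geometry(spec$image_shape, spec$lesion_side)
  rowg <- matrix(0:(nr - 1), nr, nc)
  colg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)

  in_lesion2d <- inside_ellipse(rowg, colg, g$lesion_center, g$lesion_semi)

  vox <- array(0, dim = spec$image_shape)
  mask <- array(FALSE, dim = spec$image_shape)
  for (s in seq_len(ns)) {
    # dome profile: the head narrows away from the central slice, so the
    # volume carries structure along the slice axis as well
    f <- sqrt(1 - ((s - 1 - (ns - 1) / 2) / (ns / 2 + 2))^2)
    in_brain <- inside_ellipse(rowg, colg, c(g$mr, g$mc), g$brain_semi * f)
    in_skull <- inside_ellipse(rowg, colg, c(g$mr, g$mc), g$skull_semi * f) &
      !in_brain
    in_vent <- inside_ellipse(rowg, colg, g$vent_centers[[1]], g$vent_semi * f) |
      inside_ellipse(rowg, colg, g$vent_centers[[2]], g$vent_semi * f)
    sl <- matrix(spec$background_hu, nr, nc)
    sl[in_skull] <- spec$skull_hu
    sl[in_brain] <- spec$parenchyma_hu
    sl[in_vent] <- spec$csf_hu
    if (s %in% g$lesion_slices) {
      if (any(in_lesion2d & (in_vent | in_skull | !in_brain)))
        stop("lesion region overlaps ventricle/skull/background; ",
             "adjust geometry")
      w_vox <- spec$water_uptake_w
      if (spec$w_heterogeneity > 0) {
        fld <- smooth_field(nr, nc)
        fld_les <- fld[in_lesion2d]
        fld <- (fld - mean(fld_les)) / stats::sd(fld_les) * spec$w_heterogeneity
        w_vox <- pmin(pmax(spec$water_uptake_w + fld, 0), 0.95)
        sl[in_lesion2d] <- spec$parenchyma_hu * (1 - w_vox[in_lesion2d])
      } else {
        sl[in_lesion2d] <- spec$parenchyma_hu * (1 - w_vox)
      }
      mask[s, , ] <- in_lesion2d
    }
    vox[s, , ] <- sl
  }
  if (spec$noise_sigma > 0)
    vox <- vox + stats::rnorm(length(vox), 0, spec$noise_sigma)

  vol <- ct_volume(vox, spacing = spec$spacing)
  if (!is.null(spec$misalignment)) {
    m <- spec$misalignment
    tr <- affine_transform(translation = (m$translation %||% c(0, 0, 0)) * spec$spacing,
                           rotation_deg = m$rotation_deg %||% 0,
                           scale = m$scale %||% 1)
    vol <- resample_to(vol, tr, vol, interpolation = "linear",
                       fill = spec$background_hu)
  }
  structure(list(volume = vol, lesion_mask = mask,
                 true_w = spec$water_uptake_w,
                 lesion_side = spec$lesion_side, spec = spec),
            class = "ct_phantom")
}

#' Default mirrored-patch placements for a phantom
#'
#' Places `n_pairs` patch centres at the lesion centroid on evenly spaced
#' lesion-bearing slices, emulating the four reference-slice placements of
#' the clinical procedure; optional jitter perturbs the centres to emulate
#' reader variability.
#'
#' @param phantom a `ct_phantom` from [generate_phantom()].
#' @param n_pairs number of patch pairs (default 4).
#' @param size patch edge length in voxels.
#' @param jitter integer; centres are shifted by uniform integers in
#'   `[-jitter, jitter]` per axis (uses the current RNG state).
#' @return List of [patch_spec()] objects on the ischemic side.
#' @export
phantom_patch_specs <- function(phantom, n_pairs = 4, size = 30, jitter = 0) {
  stopifnot(inherits(phantom, "ct_phantom"))
  g <- phantom_geometry(phantom$spec$image_shape, phantom$lesion_side)
  sl <- g$lesion_slices
  if (length(sl) < n_pairs)
    stop("phantom has only ", length(sl), " lesion slices; need ", n_pairs)
  pick <- sl[round(seq(1, length(sl), length.out = n_pairs))]
  lapply(pick, function(s) {
    ctr <- round(g$lesion_center)   # 0-based (row, col)
    if (jitter > 0)
      ctr <- ctr + sample(seq(-jitter, jitter), 2, replace = TRUE)
    patch_spec(slice = s - 1L, center_row = ctr[1], center_col = ctr[2],
               size = size)
  })
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults encode the study conditions this generator emulates: 39 MCE vs
#' 77 non-MCE subjects, group mean uptake 18.2% vs 8.5%, onset-to-first-scan
#' times 8.28 +/- 6.53 h vs 5.32 +/- 4.11 h, age / gender / NIHSS
#' distributions per the two groups, and a log(t+1) edema-rate link that is
#' mean-centred within each group so uptake rises with onset-to-scan time
#' while the group means stay at their specified values. MCE lesions carry
#' more within-lesion uptake heterogeneity than non-MCE lesions, so the
#' voxel-wise NWU maps (not just their mean) differ between groups.
#'
#' @param n_mce,n_non_mce group sizes (either may be 0; total >= 1).
#' @param w_mean_mce,w_mean_non group mean fractional uptake in `[0, 1)`.
#' @param w_sd_mce,w_sd_non group SD of uptake; sampled values are
#'   truncated to `[0, 1)` by rejection.
#' @param w_rate_mce,w_rate_non edema-rate coefficients of the centred
#'   `log(t + 1)` link (uptake per log-hour).
#' @param w_het_mce,w_het_non group mean within-lesion heterogeneity SD
#'   passed to [phantom_spec()]; per-subject values are drawn around these
#'   means with SD `w_het_sd`, so the two groups overlap.
#' @param w_het_sd between-subject SD of the heterogeneity parameter
#'   (truncated to `[0, 0.2]`).
#' @param age_mean,age_sd,female_prob,nihss_mean,nihss_sd,t1_mean,t1_sd,t2_mean,t2_sd
#'   length-2 numeric vectors `(MCE, non-MCE)` for the clinical covariates;
#'   times in hours from onset (first scan truncated to (0, 24], second to
#'   `> max(24, t_first)`).
#' @param image_shape,noise_sigma,parenchyma_hu forwarded to [phantom_spec()].
#' @param seed RNG seed; the cohort is a pure function of `(spec, seed)`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_mce = 39, n_non_mce = 77,
                        w_mean_mce = 0.182, w_mean_non = 0.085,
                        w_sd_mce = 0.05, w_sd_non = 0.05,
                        w_rate_mce = 0.04, w_rate_non = 0.02,
                        w_het_mce = 0.10, w_het_non = 0.04, w_het_sd = 0.03,
                        age_mean = c(64.23, 65.79), age_sd = c(11.39, 12.05),
                        female_prob = c(0.333, 0.416),
                        nihss_mean = c(11, 15), nihss_sd = c(6.83, 2.94),
                        t1_mean = c(8.28, 5.32), t1_sd = c(6.53, 4.11),
                        t2_mean = c(35.42, 36.90), t2_sd = c(8.83, 10.70),
                        image_shape = c(8, 160, 160), noise_sigma = 2,
                        parenchyma_hu = 33,
                        seed = 1L) {
  if (n_mce < 0 || n_non_mce < 0 || n_mce + n_non_mce < 1)
    stop("need at least one subject")
  for (m in c(w_mean_mce, w_mean_non))
    if (m < 0 || m >= 1) stop("group mean uptake must be in [0, 1)")
  structure(as.list(environment()), class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lower, upper, max_tries = 1000) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(max_tries)) {
      x <- stats::rnorm(1, mean, sd)
      if (x > lower && x < upper) { out[i] <- x; break }
      if (k == max_tries)
        stop("truncated sampling failed: N(", mean, ", ", sd,
             ") rarely falls in (", lower, ", ", upper, ")")
    }
  }
  out
}

#' Generate a synthetic stroke cohort with phantom CT volumes
#'
#' Draws per-subject uptake, lesion side and clinical covariates from the
#' group distributions in a [cohort_spec()], then renders one head phantom
#' per subject. Deterministic for a fixed `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `ct_cohort`; each element has `record`
#'   (one-row data.frame: subject_id, mce, age, gender, nihss, t_first,
#'   t_second, true_w), `volume`, `lesion_mask` and `lesion_side`.
#'   [cohort_table()] stacks the records.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- c(rep(TRUE, spec$n_mce), rep(FALSE, spec$n_non_mce))
  n <- length(groups)
  gi <- ifelse(groups, 1L, 2L)   # index into (MCE, non-MCE) parameter pairs

  t1 <- vapply(gi, function(g)
    rtrunc_norm(1, spec$t1_mean[g], spec$t1_sd[g], 0.25, 24), 0)
  t2 <- vapply(seq_len(n), function(i)
    rtrunc_norm(1, spec$t2_mean[gi[i]], spec$t2_sd[gi[i]],
                max(24, t1[i]), Inf), 0)

  # centred log-time edema link: group means stay at w_mean_*
  w <- numeric(n)
  for (g in 1:2) {
    idx <- which(gi == g)
    if (length(idx) == 0) next
    rate <- c(spec$w_rate_mce, spec$w_rate_non)[g]
    lt <- log(t1[idx] + 1)
    shift <- rate * (lt - mean(lt))
    mu <- c(spec$w_mean_mce, spec$w_mean_non)[g]
    sdv <- c(spec$w_sd_mce, spec$w_sd_non)[g]
    w[idx] <- vapply(shift, function(s)
      rtrunc_norm(1, mu + s, sdv, 0, 1 - 1e-9), 0)
  }

  age <- stats::rnorm(n, spec$age_mean[gi], spec$age_sd[gi])
  gender <- ifelse(stats::runif(n) < spec$female_prob[gi], "female", "male")
  nihss <- pmax(0L, as.integer(round(stats::rnorm(n, spec$nihss_mean[gi],
                                                  spec$nihss_sd[gi]))))
  side <- ifelse(stats::runif(n) < 0.5, "left", "right")
  het_mu <- ifelse(groups, spec$w_het_mce, spec$w_het_non)
  het <- vapply(het_mu, function(mu)
    if (spec$w_het_sd > 0) rtrunc_norm(1, mu, spec$w_het_sd, 0, 0.2) else mu, 0)

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(phantom_spec(
      image_shape = spec$image_shape, parenchyma_hu = spec$parenchyma_hu,
      lesion_side = side[i], water_uptake_w = w[i],
      noise_sigma = spec$noise_sigma, w_heterogeneity = het[i],
      seed = NULL))
    subjects[[i]] <- list(
      record = data.frame(subject_id = sprintf("S%03d", i), mce = groups[i],
                          age = age[i], gender = gender[i], nihss = nihss[i],
                          t_first = t1[i], t_second = t2[i], true_w = w[i],
                          stringsAsFactors = FALSE),
      volume = ph$volume, lesion_mask = ph$lesion_mask,
      lesion_side = side[i], phantom = ph)
  }
  structure(subjects, class = "ct_cohort", spec = spec)
}

#' Stack the per-subject records of a cohort into one data.frame
#' @param cohort a `ct_cohort` from [generate_cohort()].
#' @return data.frame with one row per subject.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "ct_cohort"))
  do.call(rbind, lapply(cohort, `[[`, "record"))
}
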