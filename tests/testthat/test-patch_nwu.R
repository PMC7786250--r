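test_that("mirror_center reflects across the column midline", {
  shape <- c(4, 512, 512)
  sp <- patch_spec(slice = 1, center_row = 200, center_col = 100)
  expect_equal(mirror_center(sp, shape)$center_col, 411)   # 511 - 100

  # involution over assorted valid placements
  for (col in c(30, 100, 255, 481)) {
    s <- patch_spec(1, 200, col)
    expect_equal(mirror_center(mirror_center(s, shape), shape), s)
  }

  # fixed point at the midline of an odd-width slice
  odd <- c(2, 101, 101)
  mid <- patch_spec(0, 50, 50, size = 30)
  expect_equal(mirror_center(mid, odd)$center_col, 50)

  expect_error(mirror_center(patch_spec(1, 200, 10), shape), "outside")
  expect_error(patch_spec(1, 1, 1, size = 31), "even")
})

test_that("extract_patch takes the half-open window around the centre", {
  ph <- patch_phantom(w = 0.2, noise = 0)
  # constant parenchyma region
  sp_n <- patch_spec(slice = 2, center_row = 80, center_col = 43)
  expect_equal(extract_patch(ph$volume, sp_n),
               matrix(33, 30, 30), ignore_attr = TRUE)
  # fully inside the noise-free lesion: all 26.4
  sp_l <- patch_spec(slice = 2, center_row = 80, center_col = 116)
  expect_equal(extract_patch(ph$volume, sp_l),
               matrix(33 * 0.8, 30, 30), ignore_attr = TRUE)

  # index-window oracle: element-by-element loop over the same window
  ph2 <- patch_phantom(w = 0.1, noise = 2, seed = 11)
  sp <- patch_spec(slice = 1, center_row = 77, center_col = 60, size = 10)
  got <- extract_patch(ph2$volume, sp)
  acc <- 0
  for (i in (77 - 5):(77 + 4)) for (j in (60 - 5):(60 + 4))
    acc <- acc + ph2$volume$voxels[2, i + 1, j + 1]
  expect_equal(sum(got), acc)
  expect_error(extract_patch(ph2$volume, patch_spec(9, 77, 60)), "outside")
})

test_that("validate_patch screens CSF and bone fractions", {
  expect_true(validate_patch(matrix(33, 30, 30))$valid)

  half_csf <- matrix(c(rep(5, 450), rep(33, 450)), 30, 30)
  rep_half <- validate_patch(half_csf)
  expect_false(rep_half$valid)
  expect_equal(rep_half$csf_fraction, 0.5)

  # counting oracle on a constructed mixed patch
  set.seed(4)
  mixed <- matrix(sample(c(5, 15, 33, 40, 150), 900, replace = TRUE), 30, 30)
  rep <- validate_patch(mixed)
  expect_equal(rep$csf_fraction, sum(mixed < 20) / 900)
  expect_equal(rep$bone_count, sum(mixed > 100))
})

test_that("classify_pair assigns the hypoattenuated side as ischemic", {
  a <- matrix(26.4, 30, 30); b <- matrix(33, 30, 30)
  pr <- classify_pair(a, b)
  expect_equal(pr$ischemic_side, "left")
  expect_equal(pr$d_ischemic, 26.4)
  expect_equal(pr$d_normal, 33)

  # symmetric under argument swap
  pr2 <- classify_pair(b, a)
  expect_equal(pr2$ischemic_side, "right")
  expect_equal(pr2$d_ischemic, 26.4)

  # tie-break by declared side; ambiguity error without one
  tie <- classify_pair(b, b, declared_side = "right")
  expect_equal(tie$ischemic_side, "right")
  expect_equal(compute_ip_nwu(list(tie))$ip_nwu, 0)
  expect_error(classify_pair(b, b), "ambiguous")
  expect_error(classify_pair(a, matrix(1, 2, 2)), "same shape")
})

test_that("compute_ip_nwu implements 1 - D_ischemic/D_normal", {
  mk <- function(di, dn) classify_pair(matrix(di, 30, 30), matrix(dn, 30, 30),
                                       declared_side = "left")
  same <- lapply(1:4, function(i) mk(30, 30))
  expect_equal(compute_ip_nwu(same)$ip_nwu, 0)

  pairs <- lapply(1:4, function(i) mk(24, 30))
  res <- compute_ip_nwu(pairs)
  expect_equal(res$ip_nwu, 0.2)
  expect_equal(res$per_pair_mean, 0.2)
  expect_equal(res$per_pair_nwu, rep(0.2, 4))

  neg <- lapply(1:4, function(i) mk(-5, 0))
  expect_error(compute_ip_nwu(neg), "non-physical")
})

test_that("IP-NWU recovers the phantom ground truth", {
  ph <- patch_phantom(w = 0.182, noise = 0)
  expect_equal(phantom_nwu(ph), 0.182, tolerance = 1e-12)

  # with HU noise the estimate stays within +-0.01 across seeds
  ests <- vapply(1:20, function(s)
    phantom_nwu(patch_phantom(w = 0.182, noise = 2, seed = 100 + s)), 0)
  expect_lt(abs(mean(ests) - 0.182), 0.01)
  expect_true(all(abs(ests - 0.182) < 0.01))
})

test_that("IP-NWU is ratio-scale invariant but offset-sensitive", {
  ph <- patch_phantom(w = 0.2, noise = 2, seed = 8)
  specs <- phantom_patch_specs(ph)
  base <- measure_ip_nwu(ph$volume, specs, declared_side = ph$lesion_side)

  # global multiplicative rescale leaves NWU unchanged
  ph_scaled <- ph
  ph_scaled$volume$voxels <- ph$volume$voxels * 2.7
  scaled <- measure_ip_nwu(ph_scaled$volume, specs,
                           declared_side = ph$lesion_side)
  expect_equal(scaled$nwu$ip_nwu, base$nwu$ip_nwu, tolerance = 1e-12)

  # a common additive offset strictly shrinks NWU when w > 0
  nwu_off <- vapply(c(0, 5, 10), function(off) {
    v <- ph$volume; v$voxels <- v$voxels + off
    measure_ip_nwu(v, specs, declared_side = ph$lesion_side)$nwu$ip_nwu
  }, 0)
  expect_true(all(diff(nwu_off) < 0))
})

test_that("ratio maps hold per-voxel NWU clamped to [0, 1]", {
  ph <- patch_phantom(w = 0.2, noise = 0)
  m <- measure_ip_nwu(ph$volume, phantom_patch_specs(ph),
                      declared_side = ph$lesion_side)
  expect_equal(unique(unlist(m$ratio_maps$maps)), 0.2)
  expect_equal(m$ratio_maps$clamp_count, 0)
  expect_equal(m$ratio_maps$excluded_count, 0)

  # identical patches -> all zero
  pr <- classify_pair(matrix(33, 4, 4), matrix(33, 4, 4),
                      declared_side = "left")
  expect_true(all(compute_ratio_maps(list(pr))$maps[[1]] == 0))

  # ischemic denser than its mirror -> clamped to 0 and counted;
  # near-zero normal voxels excluded and counted
  isch <- matrix(33, 4, 4); norm <- matrix(30, 4, 4)
  isch[1, 1] <- 20; norm[2, 2] <- 0.5
  pr2 <- classify_pair(norm, isch, declared_side = "left")
  pr2$ischemic <- isch; pr2$normal <- norm   # force orientation
  maps <- compute_ratio_maps(list(pr2))
  expect_equal(maps$excluded_count, 1)
  expect_true(is.na(maps$maps[[1]][2, 2]))
  expect_gte(min(maps$maps[[1]], na.rm = TRUE), 0)
  expect_equal(maps$clamp_count, sum(isch > norm) - 1)

  all_bad <- classify_pair(matrix(0.5, 2, 2), matrix(0.4, 2, 2),
                           declared_side = "left")
  expect_error(compute_ratio_maps(list(all_bad)), "excluded")
})

test_that("pooled and per-pair NWU differ only with unequal pair densities", {
  mk <- function(di, dn) classify_pair(matrix(di, 30, 30), matrix(dn, 30, 30),
                                       declared_side = "left")
  pairs <- list(mk(24, 30), mk(20, 40), mk(30, 33), mk(27, 30))
  res <- compute_ip_nwu(pairs, pooling = "pooled")
  di <- mean(c(24, 20, 30, 27)); dn <- mean(c(30, 40, 33, 30))
  expect_equal(res$pooled, 1 - di / dn)
  expect_equal(compute_ip_nwu(pairs, "per_pair")$ip_nwu,
               mean(1 - c(24, 20, 30, 27) / c(30, 40, 33, 30)))
})
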