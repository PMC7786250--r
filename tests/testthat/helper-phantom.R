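# Shared fixture builders. Patch-bearing phantoms need >= 160 voxels
# in-plane for a 30x30 patch to fit inside the lesion; geometry-only tests
# use the smaller 64x64 head.

patch_phantom <- function(w, noise = 0, seed = NULL, side = "right",
                          shape = c(6, 160, 160), het = 0) {
  generate_phantom(phantom_spec(image_shape = shape, water_uptake_w = w,
                                noise_sigma = noise, lesion_side = side,
                                w_heterogeneity = het, seed = seed))
}

small_phantom <- function(w, noise = 0, seed = NULL, side = "right") {
  generate_phantom(phantom_spec(image_shape = c(4, 64, 64),
                                water_uptake_w = w, noise_sigma = noise,
                                lesion_side = side, seed = seed))
}

# pooled IP-NWU of a phantom using its default patch placements
phantom_nwu <- function(ph, jitter = 0) {
  specs <- phantom_patch_specs(ph, jitter = jitter)
  measure_ip_nwu(ph$volume, specs, declared_side = ph$lesion_side)$nwu$ip_nwu
}

# rank-based AUC used as an independent check (not the package's code path)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
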