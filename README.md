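# ipnwu — image-patch net water uptake from non-enhanced head CT

After a large middle-cerebral-artery (MCA) stroke, some patients develop
malignant cerebral edema (MCE) — space-occupying swelling that shifts the
midline and can kill within days unless a decompressive craniectomy is
performed early. Ischemic tissue takes up water, and water hypoattenuates
on CT, so the **net water uptake**

    NWU = 1 − D_ischemic / D_normal

(the fractional density deficit of the ischemic region relative to its
mirrored contralateral reference) is an early quantitative predictor of
MCE from plain admission CT — no perfusion imaging and no lesion
segmentation required.

`ipnwu` implements this measurement and everything around it, for
neuroimaging researchers who want to study or extend CT densitometry of
stroke edema:

* **IP-NWU** — mirrored 30×30-voxel patch pairs on four axial slices;
  pooled or per-pair densitometry, CSF/bone validity screening,
  voxel-wise NWU ratio maps clamped to [0, 1].
* **SR-NWU** — the segmented-region alternative: 12-degree-of-freedom
  affine registration to a symmetric template, lesion-mask overlay and
  midline mirroring.
* **Histogram radiomics** — the N = 8 grade counts Y₁..Y₈ of the ratio
  maps plus standard deviation, min-to-max slope, Shannon entropy,
  skewness and kurtosis: 13 first-order imaging features.
* **Prediction** — SVM / logistic-regression / random-forest models with
  leave-one-out cross-validation, Mann–Whitney ROC/AUC, Youden cutoffs,
  confusion metrics including MCC, the paired DeLong AUC test, an
  exhaustive RF hyperparameter grid, and time-normalized NWU variants.
* **Agreement** — ICC(2,1), Bland–Altman limits of agreement, and
  two-group descriptive comparisons (t-test, chi-squared).
* **Synthetic data** — a mirror-symmetric head phantom with a lesion of
  known water uptake, and a two-group cohort generator with realistic
  clinical covariates, so the entire pipeline is testable end-to-end
  without patient data.

I/O: NIfTI-1 (via RNifti) and uncompressed explicit-VR little-endian
DICOM series; patch placements as CSV/JSON; a thin CLI
(`inst/scripts/ipnwu`) with `simulate`, `nwu`, `sr-nwu`, `predict` and
`agreement` subcommands.

## Worked example

```r
library(ipnwu)

# a head phantom with 20% water uptake in a right MCA lesion, HU noise SD 2
ph <- generate_phantom(phantom_spec(water_uptake_w = 0.20, noise_sigma = 2,
                                    seed = 7))

# four mirrored patch pairs at the lesion centroid, then Eq.-style NWU
specs <- phantom_patch_specs(ph)
m <- measure_ip_nwu(ph$volume, specs, declared_side = ph$lesion_side)
m$nwu
#> <nwu_result> NWU = 0.1997 (pooled; per-pair: 0.195, 0.199, 0.204, 0.200)

# the voxel-wise maps feed the 13 histogram features
h <- build_histogram(m$ratio_maps)
h$counts
#> [1]  645 2046  882   27    0    0    0    0
round(assemble_features(h, ip_nwu = m$nwu$ip_nwu, set = "nwu_imaging"), 3)
#>      nwu       y1       y2       y3       y4       y5       y6       y7
#>    0.200  645.000 2046.000  882.000   27.000    0.000    0.000    0.000
#>       y8      std    slope  entropy skewness kurtosis
#>    0.000  685.638 -682.000    1.458    1.440    0.801

# the segmented-region route from the true lesion mask agrees
compute_sr_nwu(ph$volume, ph$lesion_mask)$sr_nwu
#> [1] 0.2004072
```

The pooled IP-NWU (0.1997) and SR-NWU (0.2004) both recover the true
uptake 0.20 to about the Monte-Carlo standard error of a 3600-voxel mean
(≈ 0.0015); the histogram concentrates in grades 1–3 because the
voxel-level ratio noise (SD ≈ 0.09) spreads a 0.20-mean map across the
0–0.375 bins.

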