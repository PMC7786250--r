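---
title: "Patch-based net water uptake: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based net water uptake: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipnwu)
```

## The measurement model

Ischemic brain tissue takes up water, and water is less radiodense than
parenchyma, so an infarct hypoattenuates on CT. If a voxel of healthy
tissue with density $D_N$ (HU) takes up a water fraction $w$, its density
falls to approximately $D_I = (1 - w)\,D_N$. Inverting this gives the
net water uptake estimator at the heart of the package:

$$\mathrm{NWU} \;=\; 1 - \frac{D_\mathrm{ischemic}}{D_\mathrm{normal}}.$$

The brain's bilateral symmetry supplies the reference density: the
mirrored region in the unaffected hemisphere. `ipnwu` implements both
routes to the two densities:

* **IP-NWU** (`measure_ip_nwu()`): four mirrored pairs of 30 × 30-voxel
  patches on four axial slices through the middle-cerebral-artery
  territory. In each pair the hypoattenuated member is the ischemic
  patch. No lesion segmentation is required.
* **SR-NWU** (`compute_sr_nwu()`): a segmented lesion mask (typically
  drawn on follow-up imaging and brought into a common symmetric space)
  is overlaid on the admission scan and mirrored across the midsagittal
  plane.

Because NWU is a ratio of densities it is invariant under a global
multiplicative HU rescale, but **not** under an additive offset; a
calibration shift that adds a constant to all HU values changes NWU.
Both properties are tested.

### Pooling four patch pairs

The formula applies to one ischemic and one normal density, but four
pairs are measured. The default (`pooling = "pooled"`) computes
voxel-weighted mean densities over all ischemic and all normal patches
and applies the formula once — the four patches are treated as one
sampled ischemic core. The per-pair mean (`pooling = "per_pair"`) is also
computed and reported. On uniform lesions the two agree; they diverge
only when pair densities differ substantially.

### Voxel-wise ratio maps and the histogram features

Each pair also yields a 30 × 30 map of per-voxel NWU,
$1 - I(i,j)/N(i,j)$, computed voxel-against-mirrored-voxel. Values are
clamped into $[0, 1]$ (and the clamps counted) rather than dropped, so
the four maps always contribute exactly 3600 voxels to the histogram and
the grade counts are conserved; voxels whose mirrored reference is at or
below 1 HU have no meaningful ratio and are excluded and counted
separately. A flag (`map_value = "ratio"`) stores the raw density ratio
instead, for the alternative reading of the map.

The discrete histogram uses $N = 8$ equal-width grades over $[0, 1]$,
half-open bins with the last closed at 1. From the grade counts
$Y_1,\dots,Y_8$ five summaries are derived: the population standard
deviation; the min-to-max slope (first occurrence on ties, zero for a
constant vector); the Shannon entropy $H = -\sum p_n \log_2 p_n$ (with
$0\log 0 = 0$, bounded by 3 bits at $N = 8$); and the population skewness
and excess kurtosis of the count vector. Together with the counts these
are the 13 imaging features. Two conventions deserve note:

* **Entropy sign and base.** The defining sum is implemented in Shannon
  form (negative sign, base 2), since entropy measures average
  information content and must be non-negative; a natural-log base is
  available via the `base` argument.
* **Moments of counts, not of voxels.** Skewness and kurtosis are
  computed on the eight grade counts, with the population ($1/N$)
  normalization throughout, which keeps the $N$ in their denominators
  consistent with the standard deviation. This is the literal reading of
  the defining formulas; computing them on raw map voxels instead is a
  one-line change on the map values and was deliberately not made the
  default.

## The synthetic phantom and cohort

No patient imaging ships with the package; a geometric head phantom
stands in. It is built from concentric ellipses — a skull ring (700 HU)
around parenchyma (33 HU) with two paramedian CSF ventricles (5 HU) in
air (−1000 HU) — with a dome profile along the slice axis so the volume
carries structure in all three dimensions, and it is *exactly*
mirror-symmetric about the column midline by construction. A cylindrical
MCA-territory lesion on one side multiplies parenchymal HU by
$(1 - w)$ for a known uptake $w$; i.i.d. Gaussian HU noise (default
SD 2) is added last. Default HU values are ordinary head-CT numbers;
all are configurable. Because the uptake enters by exactly the physical
model that NWU inverts, the phantom provides an analytic ground truth:
with no noise, pooled IP-NWU and SR-NWU both equal $w$ to machine
precision, and with noise SD 2 the pooled estimate over 3600 patch
voxels has a standard error near 0.0015.

The cohort generator (`generate_cohort()`) emulates the study
conditions this pipeline targets: 39 MCE and 77 non-MCE subjects, group
mean uptake 18.2% vs 8.5% (SD 0.05, truncated to $[0,1)$), onset-to-first-scan
times 8.28 ± 6.53 h vs 5.32 ± 4.11 h, and age/gender/NIHSS drawn from
the two groups' reported distributions. Two generator-level choices are
worth recording:

* **Edema-rate link.** Uptake grows with time from onset. The generator
  applies a $\log(t+1)$ link with group-specific rates (MCE faster),
  *mean-centred within each group*, so the time trend is present while
  the group means stay exactly at their specified values rather than
  drifting with the sampled scan times.
* **Within-lesion heterogeneity.** Real infarcts are not uniform: the
  core takes up more water than the rim, and malignant edema is the more
  heterogeneous process. The generator therefore adds a smooth,
  zero-mean spatial field to $w$ inside the lesion, with a larger
  amplitude in MCE lesions (defaults 0.10 vs 0.04, between-subject SD
  0.03 so the groups overlap). Zero-mean means the subject's mean uptake
  — and hence IP-NWU — is unchanged; only the *shape* of the voxel-wise
  NWU distribution carries the extra group information. This is the
  structural feature that lets histogram radiomics add predictive value
  beyond the scalar NWU, which is precisely the phenomenon the
  prediction module exists to measure. Without it, the scalar NWU would
  be essentially Bayes-optimal on the phantom cohort and no feature set
  could beat it.

What the phantom does **not** emulate: real anatomy (gyri, grey/white
differentiation), beam hardening and other scanner artefacts,
partial-volume mixing at tissue boundaries, old lesions, and
reader-dependent patch placement against anatomical landmarks. Passing
tests on phantoms therefore validate the *estimators and their
statistics*, not clinical performance on hospital data.

## Registration and the segmented-region route

Admission and follow-up scans are aligned to a common symmetric template
with a 12-parameter affine transform (translation, rotation,
anisotropic scale, shear). A synthetic symmetric head template
(`synthetic_template()`) ships for fully self-contained use; any
standard-space template volume can be supplied by path instead.

The optimizer is deliberately simple and deterministic: a coarse-to-fine
in-plane pyramid (block-mean downsampling plus a separable 1-2-1 blur
that suppresses aliasing of the thin skull ring), staged quasi-Newton
refinement (translation, then translation+rotation+scale, then all 12
parameters), always starting from the identity. The default similarity
metric is normalized cross-correlation: both images are CT, so their
intensities are linearly related and NCC gives a smooth, sharply peaked
objective. Mutual information (`metric = "mi"`, partial-volume binned) is
provided for contrast-mismatched inputs; on the thin slabs typical of
this protocol its slice-axis component is weakly identified, so NCC is
the validated default. Volumes are interpolated trilinearly, masks by
nearest neighbour (so labels stay binary and integer-voxel shifts
conserve mask volume). Under the lesion and mirrored masks, voxel pairs
where either member leaves the 5–100 HU parenchymal window are excluded
symmetrically — the programmatic counterpart of the expert rule that
patches avoid CSF and bone.

On a thin six-slice slab, a 5% isotropic scale moves edge slices out of
the field of view and the slice-axis scale is only weakly identified;
accuracy claims for scale recovery are therefore made in-plane, where
the signal lives.

## Prediction and evaluation

Classifiers (RBF-SVM, logistic regression, random forest) are evaluated
by leave-one-out cross-validation with the positive class MCE.
Standardization, when enabled (default for the scale-sensitive SVM and
LR, off for RF), is fitted on each training fold only. The random
forest's `random_state` hyperparameter is emulated by seeding the RNG
before each fit; the grid search scores all 80 combinations of
`random_state` ∈ {2,4,…,16} × `n_estimators` ∈ {100,…,1000} by LOOCV AUC,
breaking ties toward the smaller tree count then the smaller seed. The
grid search wraps the whole LOOCV rather than nesting inside each fold,
matching the procedure it reproduces; nesting would cost an
80-fold increase in fits, and the non-nested AUC for the selected
configuration should be read with the usual optimism caveat.

AUC is the Mann–Whitney probability computed from midranks (ties count
½); the ROC curve uses thresholds at ±∞ and the midpoints between
consecutive distinct scores under the rule "score ≥ threshold is
positive", and the Youden cutoff takes the lowest threshold among
maximizers. The DeLong test uses the structural-component variance of
the paired AUC difference with a two-sided normal p-value; identical
score vectors short-circuit to $p = 1$.

One property of pooled LOOCV deserves explicit documentation: under
label permutation its mean AUC is *below* 0.5, not at it. Each held-out
subject's class is underrepresented in its own training fold, which
pushes its score toward the other class — a known pessimistic bias of
pooled cross-validated scores. The test suite asserts the absence of
optimistic bias (the leakage direction) rather than exact centring at
0.5, and measured null means of roughly 0.39–0.47 across classifiers at
n = 30–116 are the expected behaviour, not a defect.

F1 is the standard binary F1 of the positive class and is reported for
completeness, but it is not used as a headline agreement quantity. The
Matthews correlation coefficient, which uses all four confusion cells,
is computed with the convention that a zero denominator yields 0 with a
degeneracy flag.

## Agreement statistics

The intraclass correlation defaults to ICC(2,1) — two-way random
effects, absolute agreement, single measurement — computed from the
two-way ANOVA mean squares; ICC(3,1) is available by flag. Bland–Altman
analysis reports the mean difference, 1.96-SD limits of agreement
(sample SD), the count of points outside the limits, and a paired t-test
of the bias. The descriptive two-group comparisons use the classical
pooled-variance two-sample t-test (Welch by flag) and the chi-squared
test without continuity correction, so the statistic equals
$\sum (O - E)^2 / E$ exactly.

Since the package has no access to human readers, the reader-agreement
machinery is exercised with a programmatic analogue: the same phantom is
re-measured with patch centres jittered by up to ±2 voxels, emulating
two placement occasions, and the ICC across subjects is computed between
occasions. With uptake spanning 0.02–0.30 between subjects and jitter
perturbing only which uniform-lesion voxels enter a patch, this ICC is
high (> 0.99) — an upper bound on, not an estimate of, agreement between
human readers on real scans.

## Numerical conventions and degenerate inputs

* Axis order is `(slice, row, column)`, indices 0-based in patch
  placements and file interchange; the midsagittal plane is the column
  midline, and mirroring maps column $c$ to $n_\mathrm{cols} - 1 - c$.
* A 30 × 30 patch centred at $c$ covers the half-open window
  $[c - 15, c + 15)$ per axis.
* Patch validity flags CSF (< 20 HU) above a 10% fraction and any bone
  (> 100 HU) contamination; the thresholds are reporting defaults, not
  hard gates.
* Ties in `classify_pair()` (mean HU equal within $10^{-9}$) require a
  declared lesion side; without one the pair is ambiguous and an error
  is raised rather than guessing.
* Zero-variance inputs return flagged zeros (skewness/kurtosis, MCC,
  ICC) or collapse gracefully (Bland–Altman limits equal the bias) —
  never NaN.
* No CT preprocessing (smoothing, HU clipping) is applied before
  densitometry; the measurement operates on the stored HU values.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use phantoms of
6–8 slices at 160 × 160 voxels (large enough that a 30 × 30 patch and
its mirror fit inside lesion and contralateral tissue), 200-phantom
recovery and agreement banks, a 116-subject cohort per seed, and 50
seeds for the model-ordering check; registration checks run on 6 × 96 ×
96 volumes. These sizes were chosen so the entire suite runs in minutes
on one core while keeping every Monte-Carlo bound comfortably away from
its threshold.

## Known limitations

* The phantom's geometric regularity makes densitometry easier than on
  real brains; recovery error bounds here are best-case.
* Registration is affine-only, by design; no nonlinear warping, and no
  automatic patch placement (placements are explicit inputs).
* The interoperation ICC analogue quantifies pipeline stability under
  placement jitter, not human inter-reader variability.
* DICOM support covers uncompressed explicit-VR little-endian CT series
  only — sufficient for the synthetic series the package writes and for
  plain exported clinical series, but not for compressed archives.
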