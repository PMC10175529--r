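---
title: "Methods: simulating and measuring DECT radiomics robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring DECT radiomics robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrobust)
```

# Scope and model

`radrobust` studies how repeatable (scan–rescan) and reproducible
(platform-to-platform) radiomics features are when the same physical object
is imaged on different dual-energy CT platforms. Because multi-platform
phantom raw data are rarely shared, the package pairs the analysis battery
with a synthetic generator whose *only* sources of variation are the ones
the battery is meant to detect: per-platform CT-number offsets, image
noise, reconstruction-kernel-like smoothing, and repositioning between
repeated scans. Everything downstream — registration, ROI placement,
feature extraction, agreement statistics — is the same code a user would
run on real NIfTI images via `extract_study()`.

## Phantom geometry

The phantom is a 330 mm water-equivalent disk with sixteen 28 mm
cylindrical inserts: five iodine inserts (2.0, 5.0, 7.5, 10.0, 15.0 mg/mL)
and eleven tissue-mimicking rods (0.44–1.69 g/cm³). The hole layout of such
phantoms is interchangeable and no canonical assignment exists, so the
default (`default_phantom_spec()`) is a documented package convention, not
a fact about any particular physical unit: ten inserts on an outer ring
(radius 115 mm), six on an inner ring (radius 60 mm), alternating high- and
low-attenuation materials so that no two dense inserts are adjacent — the
placement that minimizes beam-hardening artifacts on a real scanner. All
centre-to-centre distances exceed 55 mm, about twice the insert diameter.

Reference CT numbers are per image type. Density rods map to HU from
lung-like (−540 HU at 0.44 g/cm³) to dense-bone-like (+990 HU at
1.69 g/cm³) on both image types; physical densities of at least
0.44 g/cm³ cannot plausibly reach −1000 HU, so the panel spans the
lung-to-bone range rather than the full air-to-bone scale. Iodine inserts
enhance only on the virtual monoenergetic image (≈ 25 HU per mg/mL at
70 keV) and sit at water-equivalent 0 HU on the virtual unenhanced image,
reflecting what material decomposition does: this single asymmetry is why
VUE and VMI behave differently downstream even before platform effects are
added.

## Platform surrogates

A `platform_model` abstracts one scanner/protocol combination with four
knobs, all in image space (no spectra, no material decomposition — vendor
physics is deliberately out of scope):

| parameter | unit | default | meaning |
|---|---|---|---|
| `hu_bias` | HU | N(0, `spread_hu`/2) | global calibration offset per image type |
| `hu_insert_deviation` | HU | N(0, `spread_hu`), `spread_hu` = 15 | per-insert CT-number deviation |
| `noise_sd` | HU | 10 | Gaussian noise SD before smoothing |
| `kernel_fwhm_px` | px | 2 | Gaussian smoothing FWHM (kernel surrogate) |

Platform 1 is the zero-deviation reference; this anchors the
identifiability of the offsets. Deviations for VMI are drawn with
`vmi_factor = 0.5` times the VUE spread, encoding the empirical observation
that monoenergetic images show lower CT-number variability across platforms
than virtual unenhanced images. Per-platform CT-number tables from physical
studies are not public, so the seeded random deviations stand in for them;
every table is user-overridable.

Noise of 10 HU and a 2 px kernel are typical of abdomen–pelvis protocols at
~20 mGy on a 512-matrix reconstruction. Kernel and noise heterogeneity
across platforms (±25% and ±20% at the nominal spread) scale linearly with
`spread_hu`, so a single knob controls "how different the platforms are"
and `spread_hu = 0` reproduces the reference platform exactly — a useful
null configuration for tests.

## Scan synthesis

`simulate_scan()` rasterizes the disk and inserts on the 512 × 512 grid
(pixel spacing 500/512 = 0.9766 mm) by the pixel-centre-in-circle rule,
then adds i.i.d. Gaussian noise and convolves with the Gaussian kernel
(separable, replicate padding). Adding noise *before* smoothing produces
the spatially correlated noise characteristic of reconstruction kernels.
Repeat 2+ scans are rigidly translated by a shift uniform in ±3 px per
axis; real repositioning magnitude is unreported in phantom protocols, so
±3 px (≈ ±3 mm) is the package's convention, and the true shift is recorded
in `applied_shift_px` as ground truth for registration tests. Everything is
a pure function of `(spec, platform, image_type, repeat, seed)`; per-scan
seeds derive deterministically from one master seed so any subset of a
study regenerates identically.

What the generator does **not** emulate: beam hardening and streaks (the
insert layout minimizes them physically, and they are absent here by
construction), partial-volume effects beyond rasterization and smoothing,
3D slice stacks (one representative 5 mm slice is modeled; the ROIs are
in-plane circles), non-Gaussian noise, and any vendor reconstruction
algorithm. Passing tests therefore demonstrate correctness of the pipeline
and the *direction* of platform effects, not the specific percentages a
physical fleet would produce.

# ROI placement and registration

Registration is translation-only: between table repositionings the phantom
cannot meaningfully rotate at this abstraction, so rotation is fixed at 0.
The similarity metric is cross-correlation of the disk-thresholded
(> −500 HU) binary silhouettes, computed by FFT, with quadratic
interpolation of the correlation peak for sub-pixel precision. The −500 HU
threshold keeps the whole disk plus a lung-insert hole, giving the
silhouette enough structure for a unique optimum.

ROIs are 26 px (25.4 mm) circles at each insert centre — comfortably inside
the 28 mm inserts, leaving a guard band against residual registration error
(tests bound it below 0.5 px). A pixel belongs to a ROI iff its centre lies
within 13 px of the ROI centre; this rule is deterministic and matches
common mask rasterization. All sixteen masks share one integer stencil (529
pixels — the lattice-point count of a radius-13 disk), so per-ROI pixel
counts are identical; the sub-pixel part of the registration moves the
stored real-valued centres, never the mask, and images are never resampled
— interpolation would contaminate the texture features.

# Feature panel

Features are computed on the original image values: no resampling,
filtering, or normalization precedes the fixed-bin-width discretization
(`level = floor((x − min)/25 HU) + 1`). Bin width 25 HU is the common CT
default when no preprocessing is applied; it is configurable. Shape
features are excluded by design — the ROIs are fixed circles, so shape
carries no information.

Class counts are 19 first-order + 24 GLCM + 14 GLDM + 16 GLRLM + 16 GLSZM
+ 5 NGTDM = 94. The widely used extractor enables 18 first-order features
by default; this package includes Standard Deviation to reach the
19-feature first-order panel, a documented convention choice.

Numerical conventions, chosen once and frozen:

* first-order moments are population (1/N) moments; Kurtosis is non-excess
  (Gaussian → 3); percentiles and quartiles use linear interpolation of
  order statistics (R type 7);
* Total Energy scales Energy by the voxel volume 0.9766² × 5 mm³ (in-plane
  spacing squared × slice thickness);
* GLCM/GLRLM use the four in-plane directions at distance 1; matrices are
  symmetric and unweighted; features are computed per direction, then
  averaged (feature-then-average);
* GLSZM zones are 8-connected components; GLDM dependence is the count of
  8-neighbours within gray-level tolerance `alpha = 0`, stored as
  dependence *size* (count + 1, including the centre pixel), which keeps
  small-dependence emphases finite; NGTDM and GLDM use only in-ROI
  neighbours at ROI edges;
* degenerate contract: constant ROIs return Entropy 0, Uniformity 1,
  Skewness/Kurtosis 0, Joint/Zone entropies 0 — never NaN. (Run-length
  entropy of a constant region is legitimately non-zero: line lengths still
  vary across the circular mask.)

Every matrix builder is tested for exact integer equality against an
independent brute-force enumeration (direct pair counting, pixel-walk run
scans, repeated-expansion zone growth, per-pixel neighbourhood scans) on
200 random grids up to 8 × 8 with up to 5 gray levels, plus conservation
laws (normalized GLCMs sum to 1; runs, zones and dependences partition the
pixel count) and 90°-rotation invariance of the direction-averaged
features.

# Agreement statistics

All statistics are implemented from their defining formulas and verified
against hand-derived worked examples and independent oracles (two-way
`aov` mean squares for ICC; rank-then-Pearson for Spearman).

* **Bland–Altman**: d = rescan − scan (sign convention documented); limits
  `bias ± 1.96·SD(d)` with the sample SD — the classical multiplier, not a
  t quantile; `frac_within` counts differences inside the limits, and zero
  SD collapses the limits onto the bias with `frac_within = 1`. The
  one-sample t test of zero bias is applied per feature across the 16 ROI
  differences; no multiple-testing correction is applied, matching common
  practice in robustness studies.
* **CV** uses |mean| so negative-valued features do not yield negative CV;
  when the mean is near zero relative to the SD the ratio is meaningless
  and the value is returned as +Inf with a degenerate flag — classified
  non-reproducible rather than dropped, since dropping would silently
  inflate reproducibility percentages.
* **QCD** needs at least four observations; with fewer platforms its
  columns are NA and never counted as reproducible.
* **Cutoffs are strict** (CV < 10, QCD < 10, ICC > 0.90, CCC > 0.90);
  boundary values fail. Degenerate (flagged) statistics fail every cutoff.
* ICC(A,1) and Lin's CCC are near-identical for two raters at n = 16
  (tested: |ICC − CCC| < 0.05 on bivariate-normal draws), which is why
  studies report near-identical ICC and CCC percentages.

# Pipeline aggregation choices

* Inter-platform analyses use the **first scan** per platform by default
  (`repeat_policy`, configurable to `second` or `mean`): whether robustness
  studies use scan, rescan, or their mean is typically unreported, so one
  convention is fixed and documented.
* Per-ROI dispersion percentages are averaged (mean ± sample SD) across the
  16 ROIs; per-pair agreement percentages across the `choose(n, 2)` pairs.
  Class rollups pool feature × ROI (or feature × pair) cells; heatmap-style
  per-feature values are ROI-averaged CV/QCD.
* Rollup means use the sample SD (n − 1). Class metric means are reported
  as fractions (a CV of 50% appears as 0.50) with degenerate values
  excluded from the mean but counted as failures in the percentage.
* The 14-feature biomarker shortlist is a configuration list shipped with
  commonly reported names — a placeholder for the user's panel of
  interest, not a prescription.
* Ranking ties are broken lexicographically; all table row orderings use
  locale-independent (radix) sorting so reports are byte-identical across
  environments and runs.

# Problem sizes and what the tests show

The test suite runs the default study — 10 platforms × 2 image types × 2
repeats, 40 simulated 512 × 512 scans — end-to-end twice to verify
byte-identical reports, plus a 10-platform single-repeat study with
heterogeneous per-insert offsets (deviations inflated fourfold on half the
inserts) for the CT-number correlation check, and several 2–5-platform
studies for unit-level properties. These sizes keep the full suite to a few
minutes while exercising the complete factorial design. Monte-Carlo
properties use 50–1000 draws as noted per test (registration recovery ≤
0.5 px over 50 seeds; ROI-mean unbiasedness within 0.5 HU over 200 seeds
with the standard error within 20% of `noise_sd/√529`; offset-recovery
regression slope within 3 SE of 1).

Two behaviours of the synthetic study deserve emphasis when comparing with
physical multi-scanner experiments:

* Qualitative orderings are reproduced — test–retest repeatability exceeds
  inter-platform reproducibility for both image types; first-order
  reproducibility is higher on VMI when its CT-number spread is configured
  lower; ROIs with larger CT-number dispersion lose more first-order
  features (negative Spearman correlation).
* Absolute percentages are *not* comparable to physical studies. In
  particular, synthetic test–retest repeatability sits below what real
  scanners achieve, because the homogeneous inserts discretize to very few
  gray levels (the ROI intensity range is mostly noise), making texture
  features sensitive to single bin-boundary flips between scan and rescan.
  Real tissue-mimicking inserts carry more intrinsic texture. The package
  reports what its model produces; it does not calibrate toward any
  published percentage.

# Known limitations

Single 2D slice; translation-only registration; Gaussian additive noise
with isotropic Gaussian kernel surrogate; no beam hardening, scatter, or
vendor reconstruction; no confidence intervals for ICC/CCC and no ICC
variants beyond (A,1); no harmonization methods (ComBat, normalization,
filtering) — those are downstream of the question this package answers,
namely how large the un-harmonized platform effect is and how it relates
to CT-number variability.
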