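# radrobust

Robustness analysis of dual-energy CT (DECT) radiomics features across
imaging platforms.

## The problem

Radiomics models extract large panels of quantitative features — intensity
statistics and gray-level texture matrices — from medical images. Their
clinical value depends on those features being *stable*: repeatable between a
scan and an immediate rescan, and reproducible when the same object is imaged
on different scanners. For DECT, where each vendor synthesizes virtual
unenhanced (VUE) and virtual monoenergetic (VMI) images with proprietary
material-decomposition pipelines, platform-to-platform differences in CT
numbers (Hounsfield units) are a suspected driver of feature instability.

`radrobust` provides, as one tested pipeline:

* a **synthetic phantom study generator** — a 330 mm water-equivalent disk
  with sixteen 28 mm inserts (five iodine concentrations, 2.0–15.0 mg/mL, and
  eleven density rods, 0.44–1.69 g/cm³), rasterized at 512 × 512 over a
  500 mm field of view for any number of surrogate platforms with
  controllable per-insert CT-number offsets, Gaussian noise,
  reconstruction-kernel-like smoothing, and rigid repositioning between
  repeats;
* **ROI tooling** — translation-only registration by FFT cross-correlation of
  the disk silhouette with sub-pixel refinement, and sixteen 26-pixel
  circular ROIs sharing one 529-pixel stencil;
* a **94-feature radiomics panel** — 19 first-order features plus 75 texture
  features (24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM) computed on
  fixed-bin-width (25 HU) discretized intensities with no image
  preprocessing, following the standard IBSI-style definitions; every matrix
  builder is verified against an independent brute-force enumeration;
* the **robustness battery** — implemented from the defining formulas:
  * Bland–Altman test–retest analysis: differences d = rescan − scan, limits
    of agreement `bias ± 1.96·SD(d)`; a feature is repeatable on a platform
    when ≥ 90% of its 16 ROI differences fall within the limits;
  * inter-platform dispersion per ROI: coefficient of variation
    `CV = 100·SD/|mean|` and quartile coefficient of dispersion
    `QCD = 100·(Q3 − Q1)/(Q3 + Q1)`, cutoff 10% (strict);
  * pairwise agreement per platform pair: ICC(A,1) — single-rater,
    absolute-agreement, two-way random effects,
    `(MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE))` — and Lin's
    concordance correlation `2·s_xy/(s_x² + s_y² + (x̄ − ȳ)²)`, cutoff 0.90
    (strict); 45 pairs per image type for 10 platforms;
  * Spearman correlation (average ranks, t-approximation p values) between
    CT-number reproducibility and the percentage of first-order features
    meeting the matching cutoff.

Scans can be written to and read from NIfTI with a CSV manifest, so the same
analysis applies to real multi-platform feature tables
(`extract_study()`, or the `analyze --features` CLI subcommand).

## Worked example

```r
library(radrobust)

platforms <- default_platform_models(n_platforms = 4, seed = 1)
study <- run_robustness_study(platforms = platforms, seed = 20)

print(study$repeatability$summary, digits = 4)
#>   image_type mean_pct sd_pct n_platforms
#> 1   VMI70keV    75.53  8.102           4
#> 2        VUE    72.07  8.438           4

print(study$dispersion$summary, digits = 4)
#>   image_type mean_pct_cv sd_pct_cv mean_pct_qcd sd_pct_qcd n_rois
#> 1   VMI70keV       20.88     5.195        36.24      9.892     16
#> 2        VUE       23.87     9.539        36.30      9.257     16

print(study$pairwise$summary, digits = 4)
#>   image_type mean_pct_icc sd_pct_icc mean_pct_ccc sd_pct_ccc n_pairs
#> 1   VMI70keV        23.23      9.643        23.05      9.766       6
#> 2        VUE        26.42     11.166        25.35     11.267       6

print(subset(study$ct$correlations, metric == "cv"), digits = 3)
#>   image_type metric    rho rho_squared        p  n undefined
#> 1   VMI70keV     cv -0.858       0.737 2.08e-05 16     FALSE
#> 5        VUE     cv -0.805       0.648 1.68e-04 16     FALSE
```

Reading the output: on each of the four simulated platforms roughly
three-quarters of the 94 features are repeatable between scan and rescan
(mean ± SD across platforms), but only ~21–24% have an inter-platform CV
below 10% (mean ± SD across the 16 ROIs) and ~23–26% exceed 0.90 ICC/CCC
between platform pairs — repeatability far exceeds reproducibility, the
hallmark of platform-driven variability. The last table shows the strong
negative Spearman correlation between a ROI's CT-number CV and the share of
its first-order features with CV < 10%: the more a ROI's CT numbers disperse
across platforms, the fewer of its intensity features survive.

`report_robustness(study, "out/")` writes the class-by-metric dispersion and
agreement tables, the per-feature heatmap values, per-ROI/per-pair
percentage tables, the top-feature ranking, the CT-number table and a JSON
run summary — byte-identical across runs with the same seed.

A thin CLI over these functions lives at `inst/cli/radrobust.R`
(`simulate`, `extract`, `analyze` subcommands with a YAML config).

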