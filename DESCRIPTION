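Package: radrobust
Title: Robustness Analysis of Dual-Energy CT Radiomics Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying the multi-platform
    robustness of radiomics features in dual-energy CT (DECT). Synthesizes
    phantom images (a 330 mm water-equivalent disk with sixteen tissue- and
    iodine-mimicking inserts) for multiple imaging platforms with controllable
    CT-number offsets, noise and reconstruction-kernel-like smoothing; performs
    rigid registration and circular-ROI extraction; computes a 94-feature
    radiomics panel (first-order, GLCM, GLDM, GLRLM, GLSZM, NGTDM) on
    fixed-bin-width discretized intensities; and runs the robustness battery:
    Bland-Altman test-retest repeatability, inter-platform coefficient of
    variation and quartile coefficient of dispersion, pairwise ICC(A,1) and
    Lin's concordance correlation, and Spearman correlation between CT-number
    variability and first-order feature reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
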