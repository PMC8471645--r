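Package: maskrepro
Title: Inter-Scan Reproducibility of 3D Segmentation Shape Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the test-retest (inter-scan) reproducibility of
    morphological shape features computed from 3D segmentation label maps, as
    used in prostate zonal segmentation studies. Reads NIfTI label volumes,
    applies largest-connected-component post-processing at configurable 3D
    connectivity, extracts 14 mesh- and moment-based shape features in physical
    units (volumes, surface area, axis lengths, elongation, flatness,
    sphericity, maximum 2D/3D diameters), and measures agreement with the Dice
    similarity coefficient, two-way random single-score intraclass correlation
    ICC(2,1) with F-based 95% confidence intervals, Bland-Altman limits of
    agreement, paired Wilcoxon tests with Benjamini-Hochberg correction,
    Spearman correlation, and a permutation test for quality-control-based
    cohort filtering. Includes a synthetic paired-cohort generator that
    emulates a two-scan study design with graded segmentation error, so the
    full pipeline can be exercised and validated without access to clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
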