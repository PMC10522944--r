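Package: mgscaffold
Title: Degradation Morphometry of Bioresorbable Magnesium Coronary
    Scaffolds from Synchrotron Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the in vivo degradation of bioresorbable
    magnesium coronary scaffolds imaged by synchrotron phase-contrast
    microtomography. Provides a parametric crown-and-link scaffold phantom
    generator with ground-truth corrosion-phase labels, vertical multi-scan
    stitching with cross-correlation refinement, a self-contained 2D U-Net
    (orthogonal-plane patch training, three-plane probability fusion) for
    4-label corrosion-phase segmentation, voxel morphometry (per-phase
    volumes and fractions, isosurface surface area, luminal/lateral/abluminal
    strut partitioning, mesh export), and the clinical statistics layer
    (late lumen loss, recoil, one-way ANOVA with Tukey-Kramer post hoc
    comparisons, rank correlation of severe degradation with inflammation
    score). All stages run end to end on synthetic phantoms, so the whole
    pipeline is testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
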