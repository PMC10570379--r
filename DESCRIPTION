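Package: shadowimg
Title: Quantitative Analysis of Shadow Fluorescence Microscopy of Brain Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing inverted-contrast ("shadow") fluorescence
    microscopy of living brain tissue, where the interstitial fluid is
    labelled and cells appear as dark silhouettes against a bright
    extracellular background. Implements extracellular-space volume-fraction
    estimation from normalized fluorescence intensity, perivascular-space and
    vessel-lumen width measurement by Gaussian line-profile fitting,
    microglial phagocytic-cup detection by fill-holes subtraction with
    content triage, process-motility metrics from tip trajectories, and
    supporting line-profile, FWHM, SNR, dye-clearance and dF/F computations.
    A seeded phantom generator produces synthetic shadow images with full
    ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    minpack.lm,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
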