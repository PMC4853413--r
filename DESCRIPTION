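Package: fcdmap
Title: Functional Connectivity Density Mapping for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise functional connectivity density (FCD) analysis for
    resting-state fMRI. Decomposes each gray-matter voxel's thresholded
    correlation degree into global, contralateral (inter-hemispheric) and
    ipsilateral (intra-hemispheric) maps, with temporal preprocessing
    (detrending, nuisance regression, band-pass filtering, optional
    Gaussian smoothing), voxel-wise group comparison with covariates under
    FDR and cluster-extent thresholding, and partial correlations between
    regional FCD and clinical severity scores. Includes a synthetic phantom
    generator with planted network structure so every stage can be
    validated against analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
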