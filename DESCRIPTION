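Package: suvrnet
Title: Regional FDG-PET SUVR Screening and Metabolic Covariance Network
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking regional brain FDG-PET metabolism to
    clinical biomarkers in metabolic disease cohorts. Computes standardized
    uptake value ratios (SUVRs) over an AAL-style 90-region parcellation with
    a cerebellar reference, applies age/sex residual correction, screens
    regions by two-group t-tests and biomarkers by covariate-adjusted partial
    correlation, builds group-level metabolic covariance networks with
    sparsity thresholding and percolation connectivity, partitions them into
    modules, and compares groups edge-wise by group-label permutation
    testing. Includes a synthetic cohort generator with planted ground truth
    (covariate confounds, block covariance, biomarker links, missingness) for
    end-to-end validation, plus BrainNet Viewer export and optional NIfTI ROI
    extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
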