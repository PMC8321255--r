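Package: radpseudo
Title: Radiomic Texture Signatures for Predicting Glioblastoma Pseudoprogression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end radiomics pipeline for predicting pseudoprogression
    in glioblastoma from pre-radiotherapy contrast-enhanced T1 MRI. Implements
    an IBSI-style catalog of 841 features (3D shape, first-order intensity
    statistics, and GLCM/GLRLM/GLSZM/GLDM/NGTDM texture features on the
    original image and on eight single-level stationary wavelet sub-bands), a
    four-stage feature-selection cascade (univariate ANOVA screening,
    Benjamini-Hochberg FDR filtering, correlation-based redundancy pruning,
    and sequential floating forward selection), and repeated stratified
    3-fold cross-validated random-forest model evaluation with ROC and
    precision-recall summaries. A synthetic cohort generator with plantable
    class effects supports fully reproducible testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    ranger,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
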