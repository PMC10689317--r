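Package: dceradiomics
Title: Radiomics Prognostic Modelling for MR and DCE-MR Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for building and evaluating
    radiomics survival models from conventional magnetic resonance (MR) and
    dynamic contrast-enhanced MR (DCE-MR) imaging. Provides a synthetic-cohort
    simulator with known ground truth (textured tumour phantoms, extended-Tofts
    DCE signal generation, proportional-hazards survival outcomes), per-voxel
    pharmacokinetic map estimation by the linearised extended Tofts model,
    IBSI-style radiomic feature extraction (shape, first-order, GLCM, GLSZM,
    GLDM and NGTDM texture families with wavelet, local-binary-pattern and
    square-root image filters), LASSO-Cox feature selection with backward
    elimination and collinearity screening, survival-model evaluation
    (Harrell's C-index, Kaplan-Meier risk stratification, log-rank tests, net
    reclassification improvement), and high-resolution sliding-window
    radiomics feature maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    survival,
    igraph,
    RNifti,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
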