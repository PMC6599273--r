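Package: mwradiomics
Title: Multi-Window CT Radiomics for Indolent Versus Aggressive Lung Nodule Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying lung nodule growth on low-dose CT with
    multi-window radiomics. Provides volume-doubling-time (VDT) computation
    and indolent/aggressive/mixed growth labelling, CT window-level
    transforms with threshold-based nodule segmentation under the lung and
    mediastinal windows, difference-region (ground-glass habitat) mask
    algebra, a 364-feature radiomic extractor (intensity, histogram,
    intensity-volume-histogram, morphology, grey-level texture matrices,
    Laws texture energies and stationary-wavelet sub-band features), the
    univariate t-test / bootstrap-AUROC / correlation-pruning / backward
    elimination feature-selection chain, logistic growth models with
    radiomics scores, bootstrap-validated performance summaries and
    nomograms, and a synthetic longitudinal part-solid nodule phantom
    generator so the whole pipeline can be exercised without protected
    screening data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
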