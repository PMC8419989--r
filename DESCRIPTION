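Package: radiopheno
Title: Radiomic Phenotype Selection and Balanced Random-Forest Diagnosis
    for Demyelinating Brain Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end radiomics analysis for differentiating multiple
    sclerosis (MS) from neuromyelitis optica (NMO) on brain MRI lesion
    masks: first-order and texture (GLCM, GLRLM, GLSZM, GLDM) feature
    extraction on original, Laplacian-of-Gaussian filtered and wavelet
    subband images; multi-level feature selection combining Wilcoxon
    scanner-robustness and class-relevance filters with a pyramid of
    random-forest sequential forward selection steps; balanced random
    forest classification under class imbalance with cross-validated and
    bootstrap evaluation including the relative standard deviation of
    AUC; exact Shapley-value interpretation of individual predictions;
    and clinical summary statistics utilities. A synthetic cohort
    generator with planted class effects and scanner batch effects makes
    every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
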