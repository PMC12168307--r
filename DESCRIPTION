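Package: renalrad
Title: Renal MRI Radiomics for Genotype Discrimination in Overgrowth Syndromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for pediatric renal MRI radiomics: phantom-based
    synthetic cohorts of paired T2-weighted and apparent-diffusion-coefficient kidney
    volumes, mask-based volumetry against an embedded normative renal-volume table,
    a 15-filter derived-image bank, a 1246-feature radiomic bank built on the five
    gray-level texture-matrix families (GLCM, GLRLM, GLSZM, GLDM, NGTDM), a staged
    feature-selection cascade (correlation screen, univariate and multivariate
    logistic regression, LASSO) with five-fold cross-validation voting, an
    8-preprocessor by 13-classifier model grid evaluated by ROC AUC, and a
    from-scratch DeLong paired AUC test with contingency-table statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
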