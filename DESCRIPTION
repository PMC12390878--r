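Package: ichmap
Title: Hematoma Location Mapping and Outcome Modeling for Spontaneous
    Intracerebral Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for template-space hematoma masks from
    spontaneous intracerebral hemorrhage (sICH): voxel-wise hemorrhage
    probability maps, atlas-region involvement quantification with the
    20-percent involvement rule, region-level group statistics
    (repeated-measures ANOVA across etiologies, per-region chi-square for
    prognosis), a compact IBSI-style radiomics extractor (first-order,
    mesh shape, GLCM, GLDM, NGTDM), attention-based multiple-instance
    pooling of per-lesion features to the patient level, L1-penalized
    logistic models (clinical, location, radiomics, score-averaged fusion)
    for three-class etiology and dichotomized mRS prognosis, and
    evaluation via macro-average one-vs-rest ROC and the DeLong test.
    Includes a synthetic-cohort generator (toy labeled atlas, etiology-
    conditional lesion placement, clinical covariates, outcome model) so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
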