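Package: stromaWD
Title: Weighted Dichotomizing Multi-Marker Prognostic Classification for
    Stromal IHC Intensities
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the Weighted Dichotomizing (WD) approach to building
    a composite prognostic classifier from a small panel of
    immunohistochemistry markers quantified in tumor-adjacent stroma on
    tissue microarrays (TMAs). Provides within-TMA median/range intensity
    normalization, censoring-aware definition of aggressive and indolent
    cases from time to biochemical recurrence, per-marker optimal-cutoff
    search with accuracy-proportional weighting, stratified k-fold
    cross-validation with accuracy/PPV/NPV/ROC-AUC, median-split
    Kaplan-Meier and Cox proportional-hazards comparisons, and a calibrated
    synthetic-cohort generator with planted ground truth for validating the
    whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Survival, Normalization, ImmunoOncology
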