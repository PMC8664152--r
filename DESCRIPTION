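Package: rtnamer
Title: Classification and Name Standardization of Radiotherapy Structure Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-modality-independent classification and renaming of prostate
    radiotherapy DICOM structure sets. Each delineated structure is rasterized to a
    3D binary mask and summarized as three orthogonal binary projections plus a
    weighted context channel ("AddMap") over all other structures; a cross-validated
    ensemble of classifiers assigns a canonical class by majority vote, three
    sequential quality-control checks (training-volume percentiles, vote agreement,
    mean winner probability) flag doubtful predictions, and a renamed DICOM
    structure-set copy is written with prescription-dose tokens carried over from
    the original names. Ships a reproducible synthetic pelvic phantom cohort
    generator so the full pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    digest,
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
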