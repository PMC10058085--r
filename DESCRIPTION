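Package: ctpffr
Title: CT Perfusion-Derived Fractional Flow Reserve on Coronary Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes fractional flow reserve (FFR) from hyperemic myocardial
    CT-perfusion maps by deriving patient-specific outlet boundary conditions:
    Voronoi perfusion territories assign myocardial voxels to coronary outlets,
    territory blood flow fixes each outlet's hyperemic resistance, and a
    reduced-order nonlinear network solver propagates mean aortic pressure
    through the coronary tree. Includes a seeded synthetic-cohort generator
    (coronary trees, stenoses, perfusion maps, invasive-FFR ground truth), the
    Renkin-Crone K1/MBF correction, and the full diagnostic-performance
    evaluation (exact binomial confidence intervals, ROC with DeLong
    comparison, McNemar, Pearson, Bland-Altman, subgroup stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
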