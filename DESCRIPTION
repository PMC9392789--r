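Package: bccs
Title: Baseline-Corrected Cell Cycle Scoring for Paired Normal and Tumour Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores bulk expression samples with a cell-cycle gene signature,
    corrects tumour scores by the median score of their normal tissue of origin
    and by tumour purity, classifies tissues into low/high cell-cycle quadrants,
    and compares low- versus high-scoring tumour groups at the driver-gene
    mutation, chromosome-arm and expression/pathway level (Fisher exact tests
    with Benjamini-Hochberg FDR, empirical-Bayes moderated differential
    expression, preranked gene-set enrichment). Includes a synthetic paired
    normal/tumour cohort generator with known ground truth for validation, plus
    readers and writers for the tabular formats involved (sample manifests,
    expression matrices as TSV or Matrix Market, GMT gene sets, purity tables,
    binary mutation matrices and chromosome-arm call matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
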