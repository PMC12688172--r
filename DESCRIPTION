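Package: ctcemt
Title: Phenotyping and Count Modelling of Circulating Tumour Cells Across
    the Epithelial-Mesenchymal Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for circulating tumour cell (CTC) studies in
    early breast cancer. Calls CTC epithelial/mesenchymal phenotypes from
    immunofluorescence marker panels and extrapolates counts to a fixed
    blood volume; selects among multi-response Poisson regression models of
    per-phenotype CTC counts by exhaustive enumeration under repeated
    10-fold cross-validation, reporting incidence rate ratios with Wald
    intervals and Nagelkerke partial pseudo-R-squared decompositions;
    scores single cells on an epithelial-mesenchymal transition (EMT) gene
    panel with quartile-based phenotype classes; classifies captured cells
    into true CTCs, potential normal cells and true normal cells from
    combined protein and transcript evidence; and performs rule-based
    differential expression calling on median-of-ratios normalized count
    matrices. A synthetic-data module generates cohort tables and
    overdispersed single-cell count matrices with the structure the
    downstream stages assume, so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
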