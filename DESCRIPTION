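Package: peptidome
Title: Label-Free Endogenous Peptidomics for Paired Lung-Lavage and Serum Fluids
Version: 0.1.0
Authors@R:
    person("Peptidome", "Maintainers", email = "maintainers@peptidome.dev",
           role = c("aut", "cre"))
Description: A pipeline for data-independent-acquisition peptidomics of paired
    bronchoalveolar lavage fluid (BALF) and serum specimens: tolerance-box
    clustering of ion events into cross-sample features, replicate
    reproducibility filtering, group-wise below-LOQ imputation, median
    centering with log2 transformation, one-way dose-response ANOVA with
    Benjamini-Hochberg FDR control, paired cross-fluid regression, and
    no-enzyme peptide-spectrum identification against a protease-substrate
    restricted database with random-decoy FDR estimation. Includes a
    synthetic-data generator emulating the paired-fluid study design so the
    full pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
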