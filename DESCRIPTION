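Package: dynpath
Title: Dynamic Pathway Analysis of Longitudinal Blood Pressure from
    Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene-based association testing of rare and common sequence
    variants against longitudinal systolic blood pressure with a
    hierarchical grouped-effect regression (multiplicative group effects
    over shrunken per-variant coefficients, fitted by a blockwise EM
    scheme of penalized least-squares steps), followed by rank-based
    pathway enrichment per exam and pathway-crosstalk network
    construction between adjacent exams. Includes treatment adjustment of
    observed blood pressure, minor-allele-frequency stratification,
    Benjamini-Hochberg correction, evaluation against a designated truth
    set (false-positive/false-negative rates, ROC/AUC), and a synthetic
    study generator emulating a small whole-genome-sequencing follow-up
    cohort so the entire workflow is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    vcfR,
    yaml
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
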