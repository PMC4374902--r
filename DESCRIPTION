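Package: ctrawb
Title: Well-Being and the Conserved Transcriptional Response to Adversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating psychological well-being to the conserved
    transcriptional response to adversity (CTRA), a leukocyte gene-expression
    signature of up-regulated pro-inflammatory genes and down-regulated Type I
    interferon and antibody-synthesis genes. Provides psychometric scoring of
    the MHC-SF and Ryff psychological well-being instruments, maximum-likelihood
    confirmatory factor analysis with nested chi-square tests, preparation of
    CTRA expression responses (quantile normalization, log2 transform,
    gene-wise standardization, sign adjustment), a pooled repeated-measures
    association model over CTRA indicator genes with heterogeneous
    compound-symmetry or unstructured within-subject covariance, and a
    synthetic-data generator with known ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    readxl,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
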