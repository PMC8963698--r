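Package: phipseqr
Title: Scaled PhIP-Seq Autoantibody Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis framework for phage immunoprecipitation sequencing
    (PhIP-Seq) autoantibody screens: gene-level normalization of peptide
    counts, fold change over mock-IP (bead-only) background, Z-scoring
    against control cohorts, multi-criterion shared-antigen hit calling,
    control-cohort downsampling analysis, L1-regularized logistic
    regression disease classification, and radioligand binding assay
    (RLBA) antibody indices. Includes a compositional
    (Dirichlet-multinomial) cohort simulator with ground-truth spike-ins
    so every stage is testable without patient sera.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
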