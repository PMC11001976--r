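Package: ampReposition
Title: Drug Repositioning Against Immunomodulatory Peptide Genes from
    Single-Cell Expression and Perturbagen Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for proposing repurposable drugs that deregulate
    immunomodulatory (antimicrobial) peptide genes in malignant versus normal
    epithelial cells. Provides a negative-binomial single-cell count simulator
    with planted effects, dropout and patient batch shifts; log-normalization,
    variance-stabilizing variable-gene selection and a two-part hurdle
    differential-expression test with a patient covariate; Pearson
    correlation modules per candidate gene with hypergeometric gene-set
    enrichment and derivation of guard gene sets (e.g. the MHC complex);
    and replicate-aggregated log-fold-change scoring of perturbagen panels
    against DMSO controls, with directional ranking, contradictory-impact
    filtering and guard-conflict reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Seurat,
    optparse,
    jsonlite
Config/testthat/edition: 3
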