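Package: rankformer
Title: Rank Value Encoding and Masked-Learning Transformer Models for
    Single-Cell Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale tooling for transcriptional masked learning on
    single-cell RNA-seq data. Implements rank value encoding tokenization
    of transcriptomes (gene non-zero-median scaling, corpus quality
    filters, DOI deduplication, tissue balancing), a scaling family of
    masked-language-model transformer encoders with exact parameter
    accounting and CPU pretraining, a rank-frequency prediction baseline
    with power-law scaling fits, contextual gene and cell embedding
    extraction with batch-robustness and separability analyses, 4-bit
    NormalFloat blockwise quantization with double quantization and
    low-rank adapters for parameter-efficient fine-tuning, and in silico
    gene deletion measured as embedding cosine shifts. Ships a seeded
    negative-binomial corpus simulator with planted cell-type programs,
    housekeeping genes and regulator-target dependencies so the whole
    stack is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    withr,
    minpack.lm,
    glmnet,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, Software
RoxygenNote: 7.3.3
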