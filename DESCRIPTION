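Package: ptmlm
Title: PTM-Aware Protein Language Modeling with Bidirectional Selective
    State-Space Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling post-translationally modified (PTM) protein
    sequences with a mixed wild-type/PTM token vocabulary. Maps UniProt-style
    PTM annotation records onto protein sequences, encodes the resulting
    proteoforms, and models them with a bidirectional selective state-space
    (Mamba-style) masked language model whose input embeddings are fused with
    a pluggable wild-type embedding backend through a sigmoid-gated linear
    layer. Includes the biased masked-LM training procedure (Adam, length
    bucketed batches, random cropping), frozen-embedding classification
    benchmarks with replicate protocol and seven binary metrics, zero-shot
    PTM discovery from masked-position logits, and deterministic synthetic
    fixture generators for sequences, PTM records and labeled tasks.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
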