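Package: attnreg
Title: Attention-Based Modeling of cis-Regulatory Element Effects on Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts gene expression from the DNA sequence and chromatin
    signal of flanking candidate cis-regulatory elements (cCREs) with a
    hierarchical transformer: an element encoder that summarises each cCRE
    into a fixed-length embedding, and a regulation encoder that models
    gene-cCRE and cCRE-cCRE interactions over genomic distance with
    relative-position attention bias and a softplus Poisson expression
    head. Gene-to-element attention weights, extracted zero-shot from the
    trained model, score enhancer-gene interactions; element-element
    attention binned at fixed genomic resolution supports insulation and
    TAD-boundary analyses. Includes a synthetic-data generator with
    planted regulatory ground truth, an Activity-by-Contact style
    baseline, and distance-stratified classification benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
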