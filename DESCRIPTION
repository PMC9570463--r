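Package: m6amnet
Title: Ensemble Attention CNN-BiLSTM Networks for m6Am Site Prediction
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts N6,2'-O-dimethyladenosine (m6Am) sites from 41-nt RNA
    windows centered on adenosine in a BCA (B = C, G or U) context. Provides
    three context-based sequence encoders (one-hot, nucleotide chemical
    property, accumulated nucleotide frequency) and their fusion; a base
    classifier built from a multi-head self-attention front-end feeding
    parallel CNN and BiLSTM branches with a two-layer softmax head,
    implemented natively in R with Adam training; a top-3 soft-voting
    ensemble selected by validation accuracy; benchmark dataset construction
    from genome FASTA and site lists (window extraction, BCA filtering,
    redundancy removal, balanced negative sampling, stratified and
    chromosome-level hold-out splits); threshold and threshold-free
    evaluation metrics with repeated stratified cross-validation; and a
    planted-motif synthetic data generator so the full pipeline is testable
    without any genomic download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
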