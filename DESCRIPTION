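Package: methformer
Title: Transformer-Based 5mC Methylation Calling from Nanopore Ionic Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects 5-methylcytosine at CpG sites from Oxford Nanopore
    ionic-signal event tables using a small Transformer encoder. Provides
    per-read signal normalization and event featurization, sinusoidal
    position embeddings (summation and concatenation variants), a
    multi-head self-attention classifier over event context windows with a
    from-scratch training loop, evaluation metrics (accuracy, precision,
    recall, F1, ROC AUC), per-site methylation frequency aggregation in
    bedMethyl-style output, and a seeded k-mer current-level simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
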