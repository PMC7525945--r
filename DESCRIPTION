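Package: essnet
Title: Sequence-Based Prediction of Bacterial Gene Essentiality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts bacterial gene essentiality from sequence alone.
    Computes an 89-value feature vector per gene (codon frequencies, GC
    content, gene length, codon adaptation index, maximum relative
    synonymous codon usage, amino-acid frequencies and protein length),
    trains a feed-forward neural network classifier on class-balanced
    corpora, and evaluates it with repeated random or orthology-cluster-aware
    train/validation/test splits so that homologous genes never leak across
    the train/test boundary. Includes a correlation-grouped feature-ablation
    study, a synthetic corpus generator with class-conditional codon-usage,
    GC and length effects and cross-species orthologous families, and a
    command-line interface for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
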