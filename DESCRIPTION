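Package: mirtarsvm
Title: miRNA Target Prediction with Multi-Objective Feature Selection and SVM Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts miRNA-mRNA target interactions from mature miRNA and
    3'UTR sequences. Detects and classifies canonical seed-match sites
    (6mer, 7mer-A1, 7mer-m8, 8mer, with a single tolerated G:U wobble),
    computes a 90-dimensional targeting-site context feature vector per
    interaction (site/flank nucleotide and dinucleotide composition,
    seed-pairing and consecutive base-pair patterns, 3'-supplementary
    pairing and AU-rich flank indicators), selects informative feature
    subsets with an archived multi-objective simulated annealing (AMOSA)
    wrapper driven by cross-validated sensitivity, specificity and Matthews
    correlation objectives of an RBF-kernel support vector machine, and
    ranks interactions by SVM decision value. Includes a synthetic
    sequence/dataset generator with planted seed sites for offline
    benchmarking, and rank-distribution and resampling comparison analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
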