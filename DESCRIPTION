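Package: lrrscan
Title: Leucine-Rich Repeat Motif Detection with a Soft-Voting Classifier Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects leucine-rich repeat (LRR) motif start positions in
    protein sequences with an ensemble of eight classifiers (RBF support
    vector machines, multi-layer perceptrons and boosted decision stumps)
    soft-voting over 16-residue profile windows. Includes the minimal and
    extended LRR pattern scanner, redundancy filters for building
    repeat-level training sets, repeat delineation and domain-coverage
    post-processing, BLOSUM-metric motif distance and silhouette/MDS
    variability analytics, and a synthetic solenoid-protein generator with
    planted ground truth for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    e1071,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
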