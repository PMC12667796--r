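Package: pioneerCoop
Title: Kinetic Modeling and In Silico Scoring of Pioneer-Factor
    Nucleosome Cooperativity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how pioneer transcription factors open
    chromatin cooperatively. Implements an out-of-equilibrium kinetic model
    of TF-nucleosome competition (4-state single-TF and 8-state two-TF
    Markov chains solved by rate-matrix nullspace), steady-state
    accessibility, dose-response curves and two-TF cooperativity over
    sampled parameter regimes; in silico motif scoring against any
    sequence-to-log-counts predictor (isolation scores via injection into
    dinucleotide-shuffled matched backgrounds, context scores via in situ
    ablation, pairwise cooperativity with a distance-binned one-tailed
    Wilcoxon test); contribution-weight-matrix scanning of per-base
    contribution tracks with seqlet-derived acceptance thresholds; and a
    synthetic-data generator that plants motifs of graded affinity with
    distance-dependent superadditive interactions for ground-truth
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
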