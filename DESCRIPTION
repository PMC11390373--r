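Package: mstlba
Title: Linear Ballistic Accumulator Modelling of the Mnemonic Similarity Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes choice and response-time behavior in the three-choice
    Mnemonic Similarity Task (MST) with a constrained three-accumulator Linear
    Ballistic Accumulator (LBA). Provides the race-model first-passage
    densities and an exact trial simulator, per-subject Bayesian and
    maximum-likelihood estimation under sum-to-one constraints on drift-rate
    means and start-point upper bounds, the Lure Discrimination Index and
    model-free behavioral summaries, Kendall tau association statistics with
    Bonferroni-Holm correction and bootstrapped correlation-difference
    intervals, test-retest stability reports, correlation of behavioral
    measures with resting-state functional-connectivity matrices (including
    the Pearson-Filon comparison of dependent overlapping correlations), and
    a ground-truth-known synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
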