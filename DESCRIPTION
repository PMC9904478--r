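Package: spikestates
Title: Metastable State Analysis of Ensemble Spike Trains with a
    Clustered Spiking Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting and interpreting metastable dynamics in
    ensemble spike trains recorded during a four-taste, two-alternative
    choice task. Provides a discrete-symbol hidden Markov model for
    simultaneously recorded spike trains (2 ms symbolization, multi-start
    Baum-Welch, BIC model selection, posterior decoding with an
    admissibility criterion), classification of decoded states by coding
    properties (taste identity, taste quality, cue and action coding) with
    chi-squared and Marascuilo post-hoc tests, warped onset-time analysis,
    surrogate-data controls (circular and swap shuffles, label
    permutations), and a clustered excitatory/inhibitory leaky
    integrate-and-fire network model of gustatory cortex that performs the
    task, including simulated optogenetic silencing experiments and
    state-sequence similarity measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
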