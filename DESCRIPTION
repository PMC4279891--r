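Package: phbvseq
Title: Sequence-Distribution Analysis of PHBV Copolymers from NMR Diad and Triad Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of the monomer sequence distribution of
    poly(3-hydroxybutyrate-co-3-hydroxyvalerate) (PHBV) copolymers. Implements
    the stationary first-order Markov model of the 3HB/3HV chain (closed-form
    diad and triad fractions, the D selectivity statistic, number-average
    block lengths, and the inverse map from composition and D to transition
    probabilities), a seeded Monte-Carlo chain simulator with empirical
    diad/triad counting, nonlinear least-squares estimation of transition
    probabilities from assigned 13C NMR peak-intensity tables, random versus
    blocky classification, a synthetic-data generator emulating a panel of
    copolymer samples, and a small command-line pipeline producing a
    per-sample report of composition, D and sequence-distribution class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
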