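Package: smfret
Title: Hidden Markov Analysis of Single-Molecule FRET Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting conformational landscapes from two-channel
    single-molecule FRET recordings of membrane receptors. Provides a
    synthetic trace generator with known ground truth, intensity corrections
    and apparent-FRET computation, automated photobleach detection and trace
    screening, global fitting of shared-variance Gaussian hidden Markov
    models across all trajectories of an experimental condition with Viterbi
    idealization, BIC-based selection of the number of conformational
    states via Gaussian mixtures, and downstream summaries: state
    populations, composite kernel-density histograms, transition density
    probability maps, dwell-time tables, and condition-to-condition
    population shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
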