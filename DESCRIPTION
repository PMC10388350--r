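Package: fretstates
Title: Photon-by-Photon Hidden Markov Modeling of Single-Molecule FRET
    Trajectories
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-molecule FRET photon trajectories from
    diffusing molecules: burst search and FRET/stoichiometry computation,
    maximum-likelihood multi-state hidden Markov inference operating on
    individual photon arrival times (with global fits sharing emission
    efficiencies across conditions), model validation by photon recoloring,
    likelihood-weighted dwell-time analysis, Viterbi segmentation and
    burst-wise fluorescence correlation, conversion of fitted rate matrices
    into stationary microstate populations and thermodynamic cycles, and
    likelihood-based ligand titration analysis with Hill-equation fitting.
    Includes an exact continuous-time Markov chain simulator of photon
    trajectories so every stage can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
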