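Package: fretdyn
Title: Single-Molecule FRET Dynamics of Multi-State Conformational Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of diffusion-based single-molecule FRET
    experiments on proteins exchanging between a small number of
    conformational ensembles. Provides a time-tagged photon-stream simulator
    with pulsed interleaved excitation (PIE), all-photon burst search and
    burst-quality filters (ALEX-2CDE, |TDX-TAA|), corrected FRET efficiency
    and stoichiometry, subpopulation time-correlated single photon counting
    (TCSPC) lifetime fitting with static and dynamic FRET lines, dynamic
    three-state photon distribution analysis (PDA) with global fitting across
    bin times, species-filtered fluorescence correlation spectroscopy (fFCS),
    and closed-form kinetics utilities (stationary occupancies, relaxation
    times, Kramers free-energy barriers) for continuous-time Markov schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
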