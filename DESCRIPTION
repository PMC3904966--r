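Package: syndyn
Title: Intrachain Dynamics and Conformations of Disordered Proteins from
    FCS and Single-Molecule FRET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring intrachain dynamics and conformational
    ensembles of intrinsically disordered protein segments, built around the
    synuclein family (alpha-, beta- and gamma-synuclein). Fits fluorescence
    correlation spectroscopy (FCS) autocorrelation curves with a combined
    translational-diffusion and self-quenching kinetic model, analyses
    single-molecule FRET burst data via corrected transfer efficiencies and
    double-Gaussian histogram fits, converts mean transfer efficiencies to
    root-mean-square end-to-end distances and radii of gyration under a
    Gaussian chain, and combines both measurements into relative intrachain
    diffusion coefficients and reconfiguration times with propagated errors.
    Includes per-residue sequence physico-chemical profiling (net charge,
    Zimmerman bulkiness, Kyte-Doolittle hydrophobicity), exact two-tailed
    Mann-Whitney U comparisons, and a synthetic-data generator (Brownian
    photon-trace simulation with two-state quenching kinetics, a multi-tau
    digital correlator, and FRET burst streams) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tibble,
    minpack.lm,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
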