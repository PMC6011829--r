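Package: hostguest
Title: Host-Guest Binding Statistics, Continuum Energetics and Activation
    Thermochemistry for Cyclodextrin Catalysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for host-guest inclusion complexes of the
    cyclodextrin type.  Computes hydrogen-bond occurrence percentages, signed
    cavity-axis depth metrics, guest RMSD after Kabsch superposition and
    two-state residence statistics from multi-frame trajectories; MM-PBSA
    style interaction-enthalpy decompositions (pairwise Coulomb and
    Lennard-Jones terms, a finite-difference linearized Poisson-Boltzmann
    polar solvation solver and a Shrake-Rupley solvent-accessible surface
    area nonpolar term); and rigid-rotor/harmonic-oscillator statistical
    thermodynamics with activation free-energy decomposition into enthalpic
    and entropic components.  A synthetic-data module generates toy
    truncated-cone hosts, stochastic binding trajectories with known ground
    truth, and thermochemistry fixtures with closed-form answers so the
    whole pipeline is testable without molecular-dynamics or
    electronic-structure outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp,
    bio3d
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
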