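Package: polhop
Title: Polariton Surface-Hopping Dynamics for Molecules in Optical Cavities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed quantum-classical simulation of molecular polariton dynamics.
    Builds the Pauli-Fierz quantum-electrodynamics potential matrix in the
    adiabatic-Fock basis (including the dipole self-energy with matter-state
    truncation), computes rigorous polariton nuclear gradients and non-adiabatic
    couplings, propagates the electronic-photonic reduced density with a split
    Runge-Kutta Lindblad integrator for cavity loss, and runs global-flux
    surface-hopping trajectory ensembles with velocity rescaling and energy-based
    decoherence. Molecular dipole surfaces and their analytic Cartesian gradients
    are provided by kernel ridge regression on Coulomb-matrix descriptors. A
    closed-form two-state torsional model molecule with harmonic Wigner sampling
    stands in for an on-the-fly electronic-structure backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
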