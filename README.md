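# polhop

Mixed quantum-classical simulation of molecular polaritons: trajectory
surface hopping on the eigensurfaces of the Pauli–Fierz quantum-
electrodynamics Hamiltonian, with Lindblad cavity loss, machine-learned
dipole surfaces, and a closed-form model photoswitch to run it all on.

## Who this is for

People studying how an optical cavity changes excited-state chemistry — here,
cis→trans photoisomerization about an N=N bond — who want a complete,
testable reference implementation of the method stack at desk scale:
polariton Hamiltonian construction, rigorous nuclear gradients, dissipative
quantum propagation, global-flux surface hopping and the associated ensemble
observables.

## The model in brief

The electronic–photonic subsystem is represented in the adiabatic-Fock basis
|φ_α(R)⟩⊗|n⟩. The potential matrix is

    V_(νn),(γm) = [E_ν(R) + ħω_c(n+½)] δ_νγ δ_nm
                + g_c (ε·μ)_νγ (√(m+1) δ_n,m+1 + √m δ_n,m−1)
                + (λ²/2) [(ε·μ)²]_νγ δ_nm ,      λ = g_c √(2/ħω_c)

with the dipole self-energy truncated to the retained electronic states.
Diagonalizing V gives polariton surfaces E^J(R); nuclei move on the active
surface with the exact Hellmann–Feynman force built from
[∇V] = ∂V/∂R + [d_af, V]. The reduced density evolves by
dρ/dt = −i[V,ρ] − [Ṙ·d_af, ρ] + Γ(LρL† − ½{L†L,ρ}) with L = I⊗â
(fourth-order Runge–Kutta, 100 substeps per 0.2 fs nuclear step), and hops
between polariton surfaces follow the global-flux prescription — velocity-
rescaled for Hamiltonian-driven hops, momentum-preserving for loss-driven
hops — plus an energy-based decoherence correction (α = 0.1 Ha). Photon
numbers use the gauge-corrected (PZW-displaced) operator
N̂ = (â†+ĝ)(â+ĝ), ĝ = (g_c/ħω_c)(ε·μ̂).

Dipole matrices and their Cartesian gradients can come from the analytic
backend or from kernel ridge regression on Coulomb-matrix descriptors
(Gaussian kernel, σ = 0.05, λ_reg = 0.005, cluster-curated training set),
with analytic prediction gradients.

The bundled backend is a 10-atom pseudo-azomethane with closed-form two-state
electronic structure along the CNNC torsion: diabats crossing tangentially at
90°, minimum adiabatic gap 2Δ = 0.04 eV, vertical excitation 2.72 eV at cis
(resonant with the cavity), a 0.8 D cis transition dipole along Y that goes
dark at trans, and a harmonic scaffold with T = 0 K Wigner sampling of its
22 vibrations. See the methods vignette
(`vignettes/polariton-dynamics.Rmd`) for every convention and design choice.

## Worked example

A 100-trajectory ensemble at g_c = 0.005 au, ħω_c = 2.72 eV, Y-polarized
field, Γ = 4 meV, 300 fs, started from the third polariton (the upper
polariton at the cis Franck–Condon point):

```r
library(polhop)
cav <- cavity_parameters(omega_c = 2.72 * polhop_units$ha_per_ev,
                         g_c = 0.005, epsilon = c(0, 1, 0),
                         n_fock = 3, gamma = 4e-3 * polhop_units$ha_per_ev)
cfg <- run_config(cav, n_steps = 1500, n_trajectories = 100,
                  seed_ic = 101, seed_hop = 7000)
res <- run_ensemble(cfg)
res$observables[c(1, 151, 301, 751, 1501),
                c("time_fs", "pop_pl_1", "pop_pl_3", "trans_fraction", "photon")]
```

```
     time_fs pop_pl_1 pop_pl_3 trans_fraction photon
1          0     0.00     1.00           0.00 0.6109
151       30     0.10     0.90           0.00 0.6157
301       60     0.18     0.81           0.00 0.5224
751      150     0.45     0.55           0.01 0.3665
1501     300     0.66     0.33           0.01 0.2088
```

Reading it: the ensemble starts purely on polariton 3 (`pop_pl_3 = 1`), which
near resonance is half photonic — hence the initial photon number ~0.6
(one-photon character plus the gauge displacement). Population relaxes to the
lowest polariton through hops (Hamiltonian-driven near the avoided crossing,
loss-driven as the cavity leaks), the photon number decays with it, and the
trans fraction stays at ~0.01: inside the cavity the isomerization is almost
completely suppressed, while the same ensemble outside the cavity
(`g_c = 0`) reaches a trans fraction of ~0.68 by 300 fs.

The same loop runs with learned dipoles: `fit_dipole_model()` trains the
kernel ridge model on backend data and
`run_config(..., engine = "reference", dipole_model = fit$model)` drives the
dynamics with it.

A thin command-line wrapper over these functions is installed at
`inst/scripts/polhop-run.R` (`Rscript polhop-run.R run --help`).

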