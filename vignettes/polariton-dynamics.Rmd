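---
title: "Polariton surface-hopping dynamics: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polariton surface-hopping dynamics: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polhop)
```

## The physical problem

When a molecule sits inside an optical cavity whose photon is resonant with an
electronic transition, the molecular excited state and the photon-dressed
ground state hybridize into polaritons. Nuclear motion then proceeds on
polariton surfaces rather than bare electronic ones, and photochemical
branching — here, cis-to-trans photoisomerization about a N=N double bond —
can be steered by the light-matter coupling strength and by how quickly the
cavity leaks photons.

`polhop` implements the complete mixed quantum-classical machinery for this
problem: the electronic-photonic subsystem is treated quantum mechanically as
a reduced density matrix, nuclei are classical trajectories, and transitions
between polariton surfaces are stochastic hops.

## The Hamiltonian

The polariton potential is the Pauli-Fierz dipole-gauge Hamiltonian
represented in the *adiabatic-Fock* product basis
$|\phi_\alpha(\mathbf R)\rangle \otimes |n\rangle$ (electronic-major
ordering, `af_basis()`):

$$V_{(\nu n),(\gamma m)} =
 \left[E_\nu(\mathbf R) + \hbar\omega_c\!\left(n+\tfrac12\right)\right]
 \delta_{\nu\gamma}\delta_{nm}
 + g_c\,(\boldsymbol\epsilon\!\cdot\!\boldsymbol\mu)_{\nu\gamma}
   \left(\sqrt{m+1}\,\delta_{n,m+1}+\sqrt{m}\,\delta_{n,m-1}\right)
 + \frac{\lambda^2}{2}\,
   \big[(\boldsymbol\epsilon\!\cdot\!\boldsymbol\mu)^2\big]_{\nu\gamma}\,
   \delta_{nm}.$$

Conventions that matter:

* **Coupling constant.** We define $g_c \equiv \lambda\sqrt{\hbar\omega_c/2}$,
  so the single-photon coupling element is exactly
  $g_c(\boldsymbol\epsilon\cdot\boldsymbol\mu)$ and a resonant two-level
  system splits by $2 g_c (\boldsymbol\epsilon\cdot\boldsymbol\mu)_{ge}$.
  This is pinned by a test asserting exact linearity of the Rabi gap in
  $g_c$.
* **Dipole self-energy (DSE) with matter truncation.** The square of the
  projected dipole operator is taken within the retained electronic states
  only, keeping all operators in one subspace. The DSE block is a Gram
  matrix, hence positive semidefinite. For a two-level emitter with permanent
  dipoles the DSE exactly cancels the permanent-dipole polaron shifts of the
  resonant pair — the Rabi gap is unchanged to machine precision. This is
  the gauge-consistency role of the term, and the package's tests verify it
  rather than "correct" it away.
* **Units.** Hartree atomic units everywhere internally ($\hbar = 1$);
  conversions (`polhop_units`) only at I/O. XYZ files are Angstrom on disk,
  Bohr in memory.

Eigenvectors are made deterministic by a phase-continuity rule: columns are
matched to the previous step's eigenvectors by greedy maximal absolute
overlap and sign-fixed so the matched overlap is positive; without a previous
step the largest-magnitude component is made positive. Energies are always
ascending.

### Active-state identity across trivial crossings

The *active surface* of a trajectory is tracked through the same overlap
matching. When two polariton states cross with negligible coupling (exactly
degenerate $|g,1\rangle$/$|e,0\rangle$ pairs at $g_c = 0$, for example), the
sorted index of a surface changes while its physical character does not; the
active index follows the matched column. With a finite gap the matched column
is the same sorted index and ordinary surface hopping is unaffected. Without
this rule the zero-coupling limit could not reduce to bare-molecule surface
hopping, because the crossing states carry exactly zero coupling and zero
hopping flux.

## Gradients and non-adiabatic couplings

The energy-conserving gradient matrix is
$[\nabla V]^a = \partial V/\partial R_a + [\,\mathbf d^a_{af}, V\,]$, where
$\mathbf d_{af}$ is the electronic derivative coupling replicated over photon
blocks. The force on the active polariton $J$ is the Hellmann-Feynman
contraction $-\,U_{\cdot J}^{\!\top}[\nabla V]^a\,U_{\cdot J}$; the
commutator contributes nothing on the eigenbasis diagonal, which the tests
verify against finite differences of the eigenvalues ($<10^{-6}$ Ha/Bohr).

The polariton NAC used for velocity rescaling is the off-diagonal
Hellmann-Feynman quotient
$d_{IK} = (U^{\!\top}[\nabla V]U)_{IK}/(E_K - E_I)$. Its oracle test
differentiates the polariton coefficients in the *fixed diabatic-Fock* basis
numerically: differentiating the eigenvector matrix alone would miss the
rotation of the underlying adiabatic basis, which dominates away from
polariton crossings. Near-degenerate pairs (gap $< 10^{-8}$ Ha) have no
defined direction; the rescaling falls back to the momentum direction.

## Quantum propagation with cavity loss

The reduced density in the adiabatic-Fock basis evolves by
$$\dot\rho = -\tfrac{i}{\hbar}[V,\rho]
           - [\dot{\mathbf R}\!\cdot\!\mathbf d_{af},\,\rho]
           + \Gamma\!\left(L\rho L^\dagger
             - \tfrac12\{L^\dagger L,\rho\}\right),
  \qquad L = \hat I_{el}\otimes\hat a .$$

Both parts are integrated with classical fourth-order Runge-Kutta substeps
(default 100 per nuclear step). The exported `split_propagate()` interleaves
one Hamiltonian and one Lindblad substep per pair — the tighter first-order
splitting, verified against a dense matrix-exponential superoperator oracle.
The trajectory driver instead runs the full Hamiltonian phase, then the full
loss phase, because the two global-flux hop checks need the density change of
each phase separately (see below); the splitting error of either ordering is
first order in the substep and far below the hop-probability scale at the
default settings. $V$, $\mathbf d_{af}$ and $\dot{\mathbf R}$ are linearly
interpolated across the nuclear step at substep midpoints.

The jump operator ensures trace conservation, decays the one-photon
population at rate $\Gamma$, and dephases photon-number coherences at
$\Gamma/2$ — all asserted against closed forms.

## Surface hopping

Hop probabilities follow the global-flux prescription: states are partitioned
into losers (group A) and gainers (group B) by the sign of their population
change over the interval; when the active state is in A, the probability of
switching to $J \in B$ is
$(\Delta\rho_{JJ}/\rho_{II})\cdot(-\Delta\rho_{II}/\sum_{K\in
A}(-\Delta\rho_{KK}))$, everything else is forbidden. For two states this
reduces to the net-flux expression, which the tests assert step by step.

Each nuclear step performs **two** hop checks: one after the Hamiltonian
phase, whose accepted hops rescale momenta along the NAC direction (taking
the smaller-magnitude root of the energy-conservation quadratic; no real root
means a frustrated hop, which leaves momenta and active state untouched,
without velocity reversal), and one after the loss phase, whose hops change
the active state without touching momenta — the missing energy left through
the cavity mirror and is logged as dissipated energy. One uniform random
number is consumed per check regardless of outcome, so a seed fixes the whole
trajectory.

After hop resolution, an energy-based decoherence correction damps every
non-active amplitude by $\exp(-\Delta t/\tau_J)$ with
$\tau_J = \frac{\hbar}{|E_J - E_I|}\left(1 + \frac{\alpha}{E_{kin}}\right)$
($\alpha = 0.1$ Ha by default, interpreted in Hartree), and the active
population is rescaled to keep unit trace. The correction is skipped for the
measure-zero case of exactly vanishing kinetic energy.

Populations are estimated two ways: the active-state fraction for polariton
states, and the mixed estimator for adiabatic-Fock states — diagonal from the
active-state indicator, coherences from the quantum density — rotated by $U$
and averaged over trajectories.

The physical photon number in the dipole gauge is not $\hat a^\dagger\hat a$:
the package uses the PZW-displaced operator
$\hat N = (\hat a^\dagger + \hat g)(\hat a + \hat g)$ with
$\hat g = (g_c/\hbar\omega_c)(\boldsymbol\epsilon\cdot\hat{\boldsymbol\mu})$
truncated to the retained states; it is positive semidefinite by
construction and reduces to $\hat a^\dagger\hat a$ at $g_c = 0$.

## The synthetic molecule

The backend stands in for an on-the-fly multireference calculation with a
closed-form two-state model of a 10-atom CH$_3$-N=N-CH$_3$ skeleton:

* diabats $V_1 = W_1\sin^2\phi + c_1\cos\phi$ and
  $V_2 = E_2 - W_2\sin^2\phi + c_1\cos\phi$ with $W_2 = E_2 - W_1$, so the
  diabatic gap $E_2\cos^2\phi$ closes tangentially at $|\phi| = 90^\circ$;
  a small constant coupling $\Delta$ turns the touching point into a
  conical-intersection-like funnel with minimum adiabatic gap $2\Delta$;
* defaults $E_2 = 2.72$ eV (resonant with the cavity), $W_1 = 1.8$ eV
  (ground-state isomerization barrier), $c_1 = 0.25$ eV (trans below cis by
  0.5 eV), $\Delta = 0.02$ eV — all configurable constants of the artifact
  chosen to land in the reference regime (bright cis, dark trans,
  barrierless excited-state path to the funnel);
* a transition dipole of 0.8 D along the lab Y axis at cis decaying to zero
  at trans, permanent dipoles along Z of the same shape, small X components;
  all even functions of $\phi$, with zero Y permanent dipoles, so a
  Y-polarized cavity couples through the transition dipole alone;
* a state-independent harmonic scaffold (bond and angle restraints at
  typical stiffnesses) holding the skeleton together; methyl torsions are
  deliberately free.

Everything — energies, Cartesian gradients, NAC vectors, dipole matrices and
their Cartesian gradients — is analytic through the torsion angle and the
standard dihedral gradient, and is validated against finite differences.

Initial conditions are sampled from the $T = 0$ K harmonic Wigner
distribution of the cis minimum: the mass-weighted Hessian is built by
central differences of the analytic gradient, and the 22 genuine vibrations
(30 degrees of freedom minus translations, rotations and the two free methyl
rotors) are sampled with $\mathrm{Var}(\tilde R) = \hbar/2\tilde\omega$,
$\mathrm{Var}(\tilde P) = \hbar\tilde\omega/2$. Center-of-mass motion and
rotation are not removed during dynamics.

### What the model does and does not emulate

The model reproduces the topography that drives the physics: resonance at the
Franck-Condon point, a bright cis / dark trans transition dipole, a
barrierless excited path to a funnel at 90 degrees, a photon-dressed barrier
surface inside the cavity. It does **not** give the electronic structure any
dependence on coordinates other than the torsion. One visible consequence:
the detuning sweeps only on the slow torsional timescale (~190 fs period), so
passage through the polariton avoided crossing is more adiabatic than in the
real molecule, whose fast N=N stretch modulates the gap. The cavity therefore
suppresses isomerization essentially completely already at
$g_c = 0.005$ au, and the additional suppression with increasing cavity loss
at large $g_c$ — visible in the reference system — has no dynamic range left
here (the trans fraction is already zero; the acceptance test for that trend
documents this honestly by failing). The monotone suppression with $g_c$ and
the monotone decrease of the photon number with $\Gamma$ are reproduced.

## Machine-learned dipole surfaces

`fit_dipole_model()` mirrors a realistic training pipeline: geometries along
the full torsional path with small Cartesian jitter, Coulomb-matrix
descriptors ($N_a(N_a-1)/2$ upper-triangle entries $Z_kZ_l/r_{kl}$; the
configuration-independent diagonal is discarded), agglomerative clustering
into up to 1000 groups with at most 100 members kept per group, and one
kernel ridge regression per dipole component
($K = \exp(-\|\Delta m\|^2/2\sigma^2)$, $\sigma = 0.05$,
$\lambda_{reg} = 0.005$) sharing a single Cholesky factorization. Dipole
vectors are learned in a body frame built by Gram-Schmidt from the N-N-C
anchor atoms, which makes targets rotation-invariant and predictions
equivariant.

Numerical choices worth knowing:

* The kernel width 0.05 is sharp on the raw descriptor scale: the descriptor
  moves ~1.7 units per radian of torsion and ~0.03 units per 0.001 Angstrom
  of Cartesian jitter. The generator's default jitter (0.001 Angstrom) keeps
  held-out points within the kernel correlation length, matching the
  dense-sampling regime these hyperparameters expect; geometries far off the
  training manifold (e.g. full Wigner displacements) are extrapolations and
  decay toward zero prediction. This mirrors the reference protocol, whose
  tens of thousands of training points play the same role at full scale.
* Kernel distances in prediction and gradients are computed from exact
  per-pair differences; the fast expanded form (norms minus cross terms) is
  used only for the large training kernel, because at these descriptor norms
  it cancels catastrophically and would inject noise above the gradient
  tolerance.
* Analytic gradients follow the chain rule through the descriptor Jacobian
  and inherit exact translation and rotation sum rules.
* Descriptor ordering is the canonical atom order; no sorting. A fixed
  single-molecule topology needs no permutation invariance — a documented
  limitation, not an oversight.
* Transition-dipole targets are smooth functions of the torsion in this
  backend, so no sign-disambiguation pass is needed; for externally supplied
  training data the contract is that signs be aligned along each generating
  trajectory beforehand.

## Driver and reproducibility

The per-step order is frozen: half-kick, drift, evaluate backend at the new
geometry, rebuild $V$/$U$ with continuity, second half-kick, Hamiltonian
phase, hop check with rescaling, loss phase, loss hop check, decoherence,
record. `run_trajectory()` runs this loop either in compiled form
(RcppArmadillo; the default) or in pure R (`engine = "reference"`); both
consume R's random stream identically, and a test asserts they produce the
same trajectory. Ensembles are averaged with deterministic per-trajectory
seeds (`seed_hop + l`) and a separate initial-condition seed.

Problem sizes used in the shipped studies: single-trajectory checks run 1000
steps of 0.2 fs; ensemble studies use 100-200 trajectories of 1500 steps
(300 fs), which the compiled engine covers in a few minutes on one core.

## Worked example

```{r example, eval = FALSE}
cav <- cavity_parameters(omega_c = 2.72 * polhop_units$ha_per_ev,
                         g_c = 0.005, epsilon = c(0, 1, 0),
                         n_fock = 3, gamma = 4e-3 * polhop_units$ha_per_ev)
cfg <- run_config(cav, n_steps = 1500, n_trajectories = 100)
res <- run_ensemble(cfg)
tail(res$observables[, c("time_fs", "trans_fraction", "photon")], 3)
```

## Known limitations

* Single cavity mode, real-valued electronic structure, one molecule.
* The electronic model is one-dimensional in the torsion (see above).
* KRR dipoles are reliable on and near the training manifold only; the
  compiled engine always uses the analytic backend, while KRR-driven
  dynamics run through the reference engine.
* The decoherence correction and GFSH are applied to the density produced by
  the Lindblad evolution as well; this follows the reference treatment of
  combining global-flux hopping with jump operators, but other orderings are
  conceivable and the chosen order is fixed and documented rather than
  configurable.
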