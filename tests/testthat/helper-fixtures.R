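# Shared fixtures built in code. Heavy objects are memoised per test run.

ha_ev <- polhop_units$ha_per_ev
OMEGA_C <- 2.72 * ha_ev         # resonant cavity photon energy (Hartree)

the_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- model_molecule()
    m
  }
})

the_wigner <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- model_wigner_spec(the_model())
    w
  }
})

std_cavity <- function(g_c = 0.005, gamma = 0, n_fock = 3,
                       epsilon = c(0, 1, 0)) {
  cavity_parameters(OMEGA_C, g_c, epsilon, n_fock = n_fock, gamma = gamma)
}

# Minimal synthetic frame with prescribed electronic quantities (defaults:
# two flat states, no couplings) for Hamiltonian-level unit tests.
make_frame <- function(energies = c(0, OMEGA_C), dipoles = NULL,
                       nacs = NULL, grads = NULL, dipole_grads = NULL,
                       n_atoms = 2) {
  n_el <- length(energies)
  ndof <- 3 * n_atoms
  coords <- matrix(seq_len(3 * n_atoms), n_atoms, 3)
  if (is.null(dipoles)) dipoles <- array(0, c(n_el, n_el, 3))
  if (is.null(nacs)) nacs <- array(0, c(n_el, n_el, ndof))
  if (is.null(grads)) grads <- matrix(0, n_el, ndof)
  electronic_frame(coords, energies, grads, nacs, dipoles, dipole_grads)
}

# Two-level frame with a pure transition dipole mu_ge along Y (and optional
# permanent dipoles along Z), resonant with OMEGA_C.
two_level_frame <- function(mu_ge = 0.25, mu_gg = 0, mu_ee = 0) {
  dip <- array(0, c(2, 2, 3))
  dip[1, 2, 2] <- dip[2, 1, 2] <- mu_ge
  dip[1, 1, 3] <- mu_gg
  dip[2, 2, 3] <- mu_ee
  make_frame(energies = c(0, OMEGA_C), dipoles = dip)
}

# random symmetric electronic dipole array
random_dipoles <- function(n_el = 2) {
  d <- array(stats::rnorm(n_el * n_el * 3), c(n_el, n_el, 3))
  for (l in 1:3) d[, , l] <- (d[, , l] + t(d[, , l])) / 2
  d
}

expect_hermitian <- function(m, tol = 1e-12) {
  expect_lt(max(Mod(m - Conj(t(m)))), tol)
}
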