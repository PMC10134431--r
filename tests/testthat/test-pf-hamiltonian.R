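test_that("dipole projection selects and combines lab components", {
  # cis transition dipole of ~0.8 D along Y projects unchanged on a Y cavity
  fr <- two_level_frame(mu_ge = 0.3147)
  emu <- project_dipole(fr, c(0, 1, 0))
  expect_equal(emu[1, 2], 0.3147)
  expect_equal(emu, t(emu))
  # orthogonal polarization sees nothing (mu^x is identically zero here)
  expect_equal(project_dipole(fr, c(1, 0, 0))[1, 2], 0)
  # oblique polarization is the componentwise linear combination
  set.seed(1)
  d <- random_dipoles()
  fr2 <- make_frame(energies = c(0, 0.1), dipoles = d)
  expect_equal(project_dipole(fr2, c(0.6, 0.8, 0)),
               0.6 * d[, , 1] + 0.8 * d[, , 2], tolerance = 1e-14)
  expect_error(project_dipole(fr, c(1, 1, 0)), "unit")
})

test_that("decoupled potential matrix is block diagonal with photon ladder", {
  fr <- two_level_frame()
  cav <- std_cavity(g_c = 0)
  basis <- af_basis(2, cav$n_fock)
  V <- build_potential_matrix(fr, cav, basis)
  expect_equal(V, diag(diag(V)))
  # |g,0> diagonal entry is E_g + omega/2 = 0.049975 Ha for a 2.72 eV photon
  expect_equal(V[af_index(basis, 1, 0), af_index(basis, 1, 0)],
               OMEGA_C / 2, tolerance = 1e-12)
  expect_equal(OMEGA_C / 2, 0.049975, tolerance = 1e-4)
})

test_that("single-photon coupling element is g_c * (eps.mu)", {
  fr <- two_level_frame(mu_ge = 0.25)
  cav <- std_cavity(g_c = 0.005, n_fock = 2)
  basis <- af_basis(2, 2)
  V <- build_potential_matrix(fr, cav, basis, include_dse = FALSE)
  expect_equal(V[af_index(basis, 1, 1), af_index(basis, 2, 0)], 1.25e-3,
               tolerance = 1e-15)
})

test_that("dipole self-energy adds lambda^2 mu_gg^2 / 2 for one state", {
  dip <- array(0, c(1, 1, 3)); dip[1, 1, 2] <- 0.5
  fr <- make_frame(energies = 0, dipoles = dip)
  # lambda = 0.1 corresponds to g_c = lambda * sqrt(omega/2)
  omega <- OMEGA_C
  g_c <- 0.1 * sqrt(omega / 2)
  cav <- cavity_parameters(omega, g_c, c(0, 1, 0), n_fock = 2)
  basis <- af_basis(1, 2)
  V0 <- build_potential_matrix(fr, cav, basis, include_dse = FALSE)
  V1 <- build_potential_matrix(fr, cav, basis, include_dse = TRUE)
  shift <- diag(V1 - V0)
  expect_equal(shift, rep(1.25e-3, 2), tolerance = 1e-12)
})

test_that("diagonalization sorts, fixes phases and tracks continuity", {
  # diagonal input: identity eigenvectors, sorted energies
  V <- diag(c(0.3, 0.1, 0.2))
  sol <- diagonalize_potential(V)
  expect_equal(sol$energies, c(0.1, 0.2, 0.3))
  expect_equal(abs(sol$U), diag(3)[, c(2, 3, 1)], tolerance = 1e-12)
  # symmetric two-level: gap 2|c|
  c0 <- 1.25e-3
  sol2 <- diagonalize_potential(matrix(c(0, c0, c0, 0), 2))
  expect_equal(diff(sol2$energies), 2 * c0, tolerance = 1e-15)
  # resonant polariton block at g_c = 0.005, eps.mu = 0.25: 2.5e-3 Ha = 68 meV
  E0 <- 0.15
  solp <- diagonalize_potential(matrix(c(E0, c0, c0, E0), 2))
  gap_mev <- diff(solp$energies) * polhop_units$ev_per_ha * 1e3
  expect_equal(gap_mev, 68.0, tolerance = 0.05)
  # continuity: slightly rotated V keeps column pairing and positive overlaps
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  V2 <- R %*% diag(c(0, 0.1)) %*% t(R)
  s1 <- diagonalize_potential(V2)
  V3 <- V2 + diag(c(1e-5, -1e-5))
  s2 <- diagonalize_potential(V3, prev_U = s1$U)
  expect_equal(s2$match, 1:2)
  expect_true(all(diag(crossprod(s1$U, s2$U)) > 0.99))
  expect_error(diagonalize_potential(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("zero-coupling polariton energies are E_alpha + omega(n + 1/2)", {
  fr <- model_electronic_frame(the_model(), phi = 0.7)
  cav <- std_cavity(g_c = 0)
  basis <- af_basis(2, 3)
  sol <- diagonalize_potential(build_potential_matrix(fr, cav, basis))
  expected <- sort(outer(OMEGA_C * (0:2 + 0.5), fr$energies, "+"))
  expect_equal(sol$energies, as.numeric(expected), tolerance = 1e-12)
})

test_that("resonant minimum gap scales linearly in g_c without the DSE", {
  fr <- two_level_frame(mu_ge = 0.25)
  basis <- af_basis(2, 2)
  gaps <- sapply(c(0.005, 0.01), function(g) {
    V <- build_potential_matrix(fr, std_cavity(g_c = g, n_fock = 2), basis,
                                include_dse = FALSE)
    e <- diagonalize_potential(V)$energies
    e[3] - e[2]
  })
  expect_equal(gaps[1], 2 * 0.005 * 0.25, tolerance = 1e-12)
  expect_equal(gaps[2] / gaps[1], 2, tolerance = 1e-10)
})

test_that("DSE block is positive semidefinite and ordering-independent", {
  set.seed(7)
  for (rep in 1:5) {
    d <- random_dipoles(3)
    fr <- make_frame(energies = c(0, 0.05, 0.12), dipoles = d)
    cav <- cavity_parameters(OMEGA_C, 0.02, c(0, 1, 0), n_fock = 3)
    emu <- project_dipole(fr, cav$epsilon)
    dse <- (cav$lambda^2 / 2) * (emu %*% emu)
    expect_gte(min(eigen(dse, symmetric = TRUE, only.values = TRUE)$values),
               -1e-14)
    basis <- af_basis(3, 3)
    V <- build_potential_matrix(fr, cav, basis)
    # permuting the basis then diagonalizing leaves sorted energies unchanged
    perm <- sample(basis$size)
    e1 <- diagonalize_potential(V)$energies
    e2 <- diagonalize_potential(V[perm, perm])$energies
    expect_equal(e1, e2, tolerance = 1e-12)
  }
})
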