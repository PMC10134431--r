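test_that("jump matrix is the photon annihilation operator on each block", {
  b2 <- af_basis(1, 2)
  expect_equal(jump_matrix(b2), matrix(c(0, 0, 1, 0), 2))
  b3 <- af_basis(1, 3)
  L3 <- jump_matrix(b3)
  expect_equal(L3[2, 3], sqrt(2))
  # applying L twice to |g,1> annihilates it
  v <- c(0, 1, 0)
  expect_equal(as.numeric(L3 %*% (L3 %*% v)), rep(0, 3))
  # two electronic states: block structure, no electronic action
  b23 <- af_basis(2, 2)
  L <- jump_matrix(b23)
  expect_equal(L, kronecker(diag(2), matrix(c(0, 0, 1, 0), 2)))
})

test_that("Hamiltonian substep reproduces closed-form unitary evolution", {
  # diagonal rho with diagonal V is stationary
  st <- quantum_state(diag(c(0.7, 0.3)) + 0i)
  V <- diag(c(0, 0.1))
  out <- hamiltonian_substep(st, V, matrix(0, 2, 2), NULL, 0.5)
  expect_equal(out$rho, st$rho, tolerance = 1e-12)
  # coherence phase rotates at the gap frequency; at t = pi/gap it is negated
  psi <- c(1, 1) / sqrt(2)
  st <- quantum_state(outer(psi, psi) + 0i)
  gap <- 0.1
  tpi <- pi / gap
  n <- 2000
  for (k in seq_len(n)) st <- hamiltonian_substep(st, V, matrix(0, 2, 2), NULL, tpi / n)
  expect_equal(Re(st$rho[1, 2]), -0.5, tolerance = 1e-8)
  expect_equal(sum(Re(diag(st$rho))), 1, tolerance = 1e-12)
  expect_hermitian(st$rho, 1e-12)
})

test_that("resonant Rabi oscillation transfers population at t = pi/Omega", {
  # two-level + photon resonant block evolves as the Rabi problem
  g_mu <- 1.25e-3
  V <- matrix(c(0.15, g_mu, g_mu, 0.15), 2)
  st <- quantum_state(diag(c(1, 0)) + 0i)
  Omega <- 2 * g_mu
  tfin <- pi / Omega
  n <- 4000
  for (k in seq_len(n)) st <- hamiltonian_substep(st, V, matrix(0, 2, 2), NULL, tfin / n)
  expect_equal(Re(st$rho[2, 2]), 1, tolerance = 1e-8)
})

test_that("Lindblad substeps follow the amplitude-damping closed form", {
  basis <- af_basis(1, 2)
  L <- jump_matrix(basis)
  gamma <- 0.002
  # rho = |1><1|: population decays exactly as exp(-Gamma t)
  st <- quantum_state(diag(c(0, 1)) + 0i)
  tgt <- 0.1 / gamma          # Gamma t = 0.1
  n <- 500
  for (k in seq_len(n)) st <- lindblad_substep(st, L, gamma, tgt / n)
  expect_equal(Re(st$rho[2, 2]), exp(-0.1), tolerance = 1e-9)
  expect_equal(Re(st$rho[2, 2]), 0.904837, tolerance = 1e-6)
  expect_equal(sum(Re(diag(st$rho))), 1, tolerance = 1e-12)
  # coherence |0><1| decays at Gamma/2
  psi <- c(1, 1) / sqrt(2)
  st2 <- quantum_state(outer(psi, psi) + 0i)
  for (k in seq_len(n)) st2 <- lindblad_substep(st2, L, gamma, tgt / n)
  expect_equal(Mod(st2$rho[1, 2]), 0.5 * exp(-0.05), tolerance = 1e-9)
  # Gamma = 0 is the identity map
  st3 <- lindblad_substep(st2, L, 0, 1)
  expect_identical(st3$rho, st2$rho)
})

test_that("split propagation matches the exact Lindblad superoperator", {
  # dense superoperator oracle on a 4-dimensional system (2 el x 2 fock)
  basis <- af_basis(2, 2)
  K <- basis$size
  L <- jump_matrix(basis)
  gamma <- 0.004
  set.seed(9)
  Vr <- crossprod(matrix(stats::rnorm(K * K, sd = 0.05), K))
  Dr <- matrix(stats::rnorm(K * K, sd = 0.01), K); Dr <- (Dr - t(Dr)) / 2
  psi <- complex(real = stats::rnorm(K), imaginary = stats::rnorm(K))
  psi <- psi / sqrt(sum(Mod(psi)^2))
  rho0 <- outer(psi, Conj(psi))
  # exact propagator: vec(rho') = expm(t S) vec(rho)
  Id <- diag(K)
  S <- -1i * (kronecker(Id, Vr) - kronecker(t(Vr), Id)) -
    (kronecker(Id, Dr) - kronecker(t(Dr), Id)) +
    gamma * (kronecker(Conj(L), L) -
               0.5 * (kronecker(Id, crossprod(L)) + kronecker(t(crossprod(L)), Id)))
  es <- eigen(S)
  expm_S <- function(t) es$vectors %*% diag(exp(t * es$values)) %*% solve(es$vectors)
  tstep <- 40
  exact <- matrix(expm_S(tstep) %*% as.vector(rho0), K)
  err <- sapply(c(50, 100), function(nsub) {
    out <- split_propagate(quantum_state(rho0), Vr, Dr, NULL, L, gamma,
                           dt_nuclear = tstep, n_sub = nsub)
    max(Mod(out$rho - exact))
  })
  # first-order splitting: halving the substep shrinks the error ~2x
  expect_gte(err[1] / err[2], 1.9)
  expect_lt(err[2], 1e-3)
  # gamma = 0 reduces to pure Hamiltonian evolution bitwise
  a <- split_propagate(quantum_state(rho0), Vr, Dr, NULL, L, 0, tstep, 50)
  st <- quantum_state(rho0)
  for (k in seq_len(50)) st <- hamiltonian_substep(st, Vr, Dr, NULL, tstep / 50)
  expect_identical(a$rho, st$rho)
})

test_that("pure loss cascade matches the closed-form birth-death solution", {
  # V = 0, D = 0, n_fock = 3: |2> decays at 2*Gamma into |1>, |1> at Gamma
  basis <- af_basis(1, 3)
  L <- jump_matrix(basis)
  gamma <- 0.003
  rho0 <- diag(c(0, 0, 1)) + 0i
  tfin <- 300
  st <- quantum_state(rho0)
  nstep <- 10
  for (k in seq_len(nstep)) {
    st <- split_propagate(st, matrix(0, 3, 3), matrix(0, 3, 3), NULL, L,
                          gamma, tfin / nstep, n_sub = 100)
  }
  gt <- gamma * tfin
  p2 <- exp(-2 * gt)
  p1 <- 2 * exp(-gt) * (1 - exp(-gt))        # solution of the cascade ODEs
  p0 <- 1 - p1 - p2
  expect_equal(Re(diag(st$rho)), c(p0, p1, p2), tolerance = 1e-8)
  # long-time fixed point is the photon vacuum
  for (k in seq_len(40)) {
    st <- split_propagate(st, matrix(0, 3, 3), matrix(0, 3, 3), NULL, L,
                          gamma, tfin, n_sub = 100)
  }
  expect_equal(Re(diag(st$rho)), c(1, 0, 0), tolerance = 1e-6)
})

test_that("quantum_state validates its invariants", {
  expect_error(quantum_state(diag(c(0.6, 0.6)) + 0i), "trace")
  m <- matrix(c(0.5, 0.2, 0.3, 0.5), 2) + 0i
  expect_error(quantum_state(m), "Hermitian")
  bad <- diag(c(1.2, -0.2)) + 0i
  expect_error(quantum_state(bad), "positive")
})
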