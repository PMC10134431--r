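test_that("adiabatic-Fock NAC replicates the electronic NAC per photon block", {
  fr <- model_electronic_frame(the_model(), phi = 1.0)
  basis <- af_basis(2, 2)
  d_af <- nac_adiabatic_fock(fr, basis)
  v <- fr$nacs[1, 2, ]
  for (n in 0:1) {
    i <- af_index(basis, 1, n); j <- af_index(basis, 2, n)
    expect_equal(d_af[i, j, ], v)
    # cross-photon-number entries vanish
    expect_equal(d_af[i, af_index(basis, 2, 1 - n), ], rep(0, 30))
  }
  # antisymmetry per degree of freedom
  for (a in seq(1, 30, by = 7)) {
    expect_equal(d_af[, , a], -t(d_af[, , a]))
  }
  # a single electronic state has no coupling
  dip <- array(0, c(1, 1, 3))
  fr1 <- make_frame(energies = 0, dipoles = dip)
  expect_true(all(nac_adiabatic_fock(fr1, af_basis(1, 3)) == 0))
})

test_that("potential-matrix gradient matches finite differences of V", {
  model <- the_model()
  cav <- std_cavity(g_c = 0.005)
  basis <- af_basis(2, 3)
  co <- generate_geometry(0.8, noise_amplitude = 0.01, seed = 3)
  fr <- model_electronic_frame(model, coords = co)
  dV <- grad_potential_matrix(fr, cav, basis)
  h <- 1e-4
  for (d in c(2, 7, 11, 23)) {
    at <- (d - 1) %/% 3 + 1; xyz <- (d - 1) %% 3 + 1
    cp <- co; cm <- co
    cp[at, xyz] <- cp[at, xyz] + h; cm[at, xyz] <- cm[at, xyz] - h
    Vp <- build_potential_matrix(model_electronic_frame(model, coords = cp), cav, basis)
    Vm <- build_potential_matrix(model_electronic_frame(model, coords = cm), cav, basis)
    expect_equal(dV[, , d], (Vp - Vm) / (2 * h), tolerance = 1e-7)
  }
  # missing dipole gradients give an actionable error
  fr2 <- make_frame()
  expect_error(grad_potential_matrix(fr2, cav, af_basis(2, 3)), "dipole gradients")
})

test_that("full gradient matrix equals the brute-force commutator form", {
  set.seed(11)
  K <- 4; ndof <- 5
  dV <- array(stats::rnorm(K * K * ndof), c(K, K, ndof))
  d_af <- array(stats::rnorm(K * K * ndof), c(K, K, ndof))
  for (a in seq_len(ndof)) {
    dV[, , a] <- (dV[, , a] + t(dV[, , a])) / 2
    d_af[, , a] <- (d_af[, , a] - t(d_af[, , a])) / 2
  }
  Vr <- crossprod(matrix(stats::rnorm(K * K), K))
  g <- full_gradient_matrix(dV, d_af, Vr)
  for (a in seq_len(ndof)) {
    expect_equal(g[, , a], dV[, , a] + d_af[, , a] %*% Vr - Vr %*% d_af[, , a],
                 tolerance = 1e-13)
  }
  # zero NAC leaves the bare derivative
  expect_equal(full_gradient_matrix(dV, array(0, dim(dV)), Vr), dV)
  # the commutator contributes nothing on the eigenbasis diagonal
  sol <- diagonalize_potential(Vr)
  for (a in seq_len(ndof)) {
    full_d <- diag(crossprod(sol$U, g[, , a] %*% sol$U))
    bare_d <- diag(crossprod(sol$U, dV[, , a] %*% sol$U))
    expect_equal(full_d, bare_d, tolerance = 1e-12)
  }
})

# shared helper: everything needed for force/NAC oracles at one geometry
polariton_at <- function(co, cav, basis, model = the_model()) {
  fr <- model_electronic_frame(model, coords = co)
  V <- build_potential_matrix(fr, cav, basis)
  sol <- diagonalize_potential(V)
  d_af <- nac_adiabatic_fock(fr, basis)
  dV <- grad_potential_matrix(fr, cav, basis)
  list(fr = fr, V = V, sol = sol,
       gradV = full_gradient_matrix(dV, d_af, V))
}

test_that("active force reduces to the bare gradient at zero coupling", {
  co <- generate_geometry(0.5)
  basis <- af_basis(2, 3)
  p <- polariton_at(co, std_cavity(g_c = 0), basis)
  # find the |e,0>-dominated polariton
  J <- which.max(p$sol$U[af_index(basis, 2, 0), ]^2)
  F <- active_force(p$sol, p$gradV, J)
  expect_equal(F, -p$fr$grads[2, ], tolerance = 1e-10)
  expect_error(active_force(p$sol, p$gradV, 99), "out of range")
})

test_that("state-averaged force reproduces the gradient trace identity", {
  set.seed(2)
  co <- generate_geometry(1.1, noise_amplitude = 0.01)
  basis <- af_basis(2, 3)
  p <- polariton_at(co, std_cavity(g_c = 0.02), basis)
  K <- basis$size
  total <- Reduce(`+`, lapply(seq_len(K), function(J)
    active_force(p$sol, p$gradV, J)))
  tr <- sapply(seq_len(dim(p$gradV)[3]), function(a) sum(diag(p$gradV[, , a])))
  expect_equal(total, -tr, tolerance = 1e-10)
})

test_that("polariton NAC obeys its limits and antisymmetry", {
  basis <- af_basis(2, 3)
  co <- generate_geometry(0.9)
  p0 <- polariton_at(co, std_cavity(g_c = 0), basis)
  # map sorted polariton index -> (el, n) at zero coupling
  char_of <- apply(p0$sol$U^2, 2, which.max)
  lab <- basis$index_map[char_of, ]
  same_n <- which(lab$n == lab$n[1] & lab$el != lab$el[1])[1]
  d <- nac_polariton(p0$sol, p0$gradV, 1, same_n)
  s <- sign(sum(d * p0$fr$nacs[1, 2, ]))
  expect_equal(d, s * p0$fr$nacs[1, 2, ], tolerance = 1e-10)
  # photon-number-changing pair decouples
  diff_n <- which(lab$el == lab$el[1] & lab$n != lab$n[1])[1]
  expect_equal(max(abs(nac_polariton(p0$sol, p0$gradV, 1, diff_n))), 0,
               tolerance = 1e-12)
  # antisymmetry at finite coupling
  p <- polariton_at(co, std_cavity(g_c = 0.02), basis)
  expect_equal(nac_polariton(p$sol, p$gradV, 2, 4),
               -nac_polariton(p$sol, p$gradV, 4, 2), tolerance = 1e-12)
  expect_error(nac_polariton(p$sol, p$gradV, 2, 2), "differ")
})
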