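test_that("polariton-basis transformation is unitary and exact on 2x2 cases", {
  set.seed(3)
  K <- 4
  psi <- complex(real = stats::rnorm(K), imaginary = stats::rnorm(K))
  psi <- psi / sqrt(sum(Mod(psi)^2))
  rho <- outer(psi, Conj(psi))
  expect_equal(to_polariton_density(rho, diag(K)), rho)
  U <- qr.Q(qr(matrix(stats::rnorm(K * K), K)))
  rp <- to_polariton_density(rho, U)
  expect_equal(Re(sum(diag(rp))), 1, tolerance = 1e-13)
  # round trip
  expect_equal(to_polariton_density(U %*% rp %*% t(U), U), rp, tolerance = 1e-12)
  # pure basis state under a 45-degree rotation
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rp2 <- to_polariton_density(diag(c(1, 0)) + 0i, R)
  expect_equal(Re(diag(rp2)), c(0.5, 0.5))
  expect_equal(Mod(rp2[1, 2]), 0.5)
})

test_that("GFSH probabilities implement the flux partition", {
  # two states: active loses 0.1 out of 0.9 -> p = 1/9
  r1 <- diag(c(0.9, 0.1)); r2 <- diag(c(0.8, 0.2))
  p <- gfsh_probabilities(r1, r2, 1)
  expect_equal(p[2], 0.1 / 0.9, tolerance = 1e-12)
  expect_equal(p[1], 0)
  # active state gaining population forbids all hops
  expect_equal(gfsh_probabilities(r1, r2, 2), c(0, 0))
  # three states: flux split in the gainers' ratio
  r1 <- diag(c(0.5, 0.3, 0.2)); r2 <- diag(c(0.4, 0.36, 0.24))
  p3 <- gfsh_probabilities(r1, r2, 1)
  expect_equal(p3[2] / p3[3], 0.06 / 0.04, tolerance = 1e-12)
  expect_equal(sum(p3), 0.1 / 0.5, tolerance = 1e-12)
  # destinations in the losing group get zero
  r2b <- diag(c(0.45, 0.35, 0.2))
  p3b <- gfsh_probabilities(r1, r2b, 1)
  expect_equal(p3b[3], 0)
  # numerically negative loss from a zero-population active state: warning
  expect_warning(pz <- gfsh_probabilities(diag(c(0, 1)),
                                          diag(c(-1e-12, 1 + 1e-12)), 1),
                 "zero")
  expect_equal(pz, c(0, 0))
})

test_that("two-state GFSH equals the net population-flux expression", {
  # oracle: with two states the destination probability must reduce to
  # max(0, -delta_II) / rho_II
  set.seed(21)
  for (rep in 1:500) {
    p0 <- stats::runif(1, 0.05, 0.95)
    d <- stats::runif(1, -0.3, 0.3)
    p1 <- min(max(p0 + d, 0), 1)
    r1 <- diag(c(p0, 1 - p0)); r2 <- diag(c(p1, 1 - p1))
    p <- gfsh_probabilities(r1, r2, 1)
    expect_equal(p[2], max(0, -(p1 - p0)) / p0, tolerance = 1e-12)
    expect_lte(sum(p), 1 + 1e-12)
  }
})

test_that("hop sampling is reproducible and matches binomial statistics", {
  expect_true(is.na({set.seed(1); attempt_hop(c(0, 0, 0))}))
  expect_equal({set.seed(1); attempt_hop(c(0, 1, 0))}, 2L)
  probs <- c(0.3, 0.2)
  n <- 1e5
  set.seed(123)
  draws <- replicate(n, attempt_hop(probs))
  f1 <- mean(draws == 1, na.rm = FALSE)
  f1 <- sum(draws == 1, na.rm = TRUE) / n
  f2 <- sum(draws == 2, na.rm = TRUE) / n
  expect_lt(abs(f1 - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_lt(abs(f2 - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  # determinism under a fixed seed
  set.seed(77); a <- replicate(100, attempt_hop(probs))
  set.seed(77); b <- replicate(100, attempt_hop(probs))
  expect_identical(a, b)
})

test_that("velocity rescaling conserves energy and flags frustrated hops", {
  # 1D: m = 1, p = 2 (KE = 2), hop up by 1.5 -> p' = 1
  rs <- rescale_velocity(P = c(2), masses = c(1), d_IK = c(1), deltaE = 1.5)
  expect_false(rs$frustrated)
  expect_equal(rs$P, 1, tolerance = 1e-12)
  # deltaE = 0 leaves momenta untouched
  rs0 <- rescale_velocity(c(2), c(1), c(1), 0)
  expect_equal(rs0$kappa, 0)
  expect_equal(rs0$P, 2)
  # insufficient kinetic energy along the NAC: frustrated, momenta unchanged
  rsf <- rescale_velocity(c(2), c(1), c(1), 5)
  expect_true(rsf$frustrated)
  expect_equal(rsf$P, 2)
  # multidimensional energy conservation
  set.seed(5)
  m <- rep(c(2000, 3000), each = 3)
  P <- stats::rnorm(6, sd = 20)
  d <- stats::rnorm(6)
  dE <- 0.01
  rs2 <- rescale_velocity(P, m, d, dE)
  if (!rs2$frustrated) {
    ke0 <- sum(P^2 / (2 * m)); ke1 <- sum(rs2$P^2 / (2 * m))
    expect_equal(ke1 - ke0, -dE, tolerance = 1e-10)
  }
  expect_warning(rescale_velocity(c(2), c(1), c(0), 0.1), "momentum")
})

test_that("loss-channel hops never touch momenta and log dissipation", {
  # equal densities (Gamma = 0): no hop possible
  r <- diag(c(0.5, 0.5)) + 0i
  set.seed(2)
  out <- loss_hop_channel(r, r, 1, c(0, 0.1))
  expect_false(out$hopped)
  # guaranteed hop: all of the active population flows down
  r1 <- diag(c(0, 1)) + 0i; r2 <- diag(c(1, 0)) + 0i
  set.seed(2)
  out2 <- loss_hop_channel(r1, r2, 2, energies = c(0.05, 0.15))
  expect_true(out2$hopped)
  expect_equal(out2$active, 1L)
  expect_equal(out2$dissipated, 0.1)
})

test_that("decoherence correction damps coherences at the stated rate", {
  # two-state: gap 0.1 Ha, Ekin 0.05 Ha, dt 8.27 au -> tau 30 au, factor 0.7595
  rho <- matrix(c(0.9, 0.3, 0.3, 0.1), 2) + 0i
  energies <- c(0, 0.1)
  out <- decoherence_correction(rho, active = 1, energies, Ekin = 0.05,
                                dt = 8.27, alpha = 0.1)
  f <- exp(-8.27 / 30)
  expect_equal(f, 0.7595, tolerance = 1e-3)
  # non-active population damps by f^2; coherence by f * (active factor)
  expect_equal(Re(out[2, 2]), 0.1 * f^2, tolerance = 1e-12)
  expect_equal(Mod(out[1, 2]), 0.3 * f * sqrt((1 - 0.1 * f^2) / 0.9),
               tolerance = 1e-12)
  expect_equal(Re(sum(diag(out))), 1, tolerance = 1e-12)
  # degenerate states are not damped
  out2 <- decoherence_correction(rho, 1, c(0.2, 0.2), 0.05, 8.27)
  expect_equal(out2, rho / Re(sum(diag(rho))), tolerance = 1e-12)
  expect_error(decoherence_correction(rho, 1, energies, Ekin = 0, dt = 1), "Ekin")
})
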