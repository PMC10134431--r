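test_that("Coulomb descriptor has the right entries, length and invariances", {
  # two protons at 1 Bohr
  co <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(coulomb_descriptor(co, c(1, 1)), 1.0)
  # 10-atom molecule: 45 pair entries
  co10 <- generate_geometry(0.4)
  z10 <- c(6, 7, 7, 6, rep(1, 6))
  m <- coulomb_descriptor(co10, z10)
  expect_length(m, 45)
  expect_true(all(m > 0))
  # rigid rotation and translation leave the descriptor unchanged
  set.seed(8)
  R <- polhop:::random_rotation()
  co_rot <- t(R %*% t(co10)) + matrix(rep(c(1, -2, 3), each = 10), 10, 3)
  expect_equal(coulomb_descriptor(co_rot, z10), m, tolerance = 1e-12)
  expect_error(coulomb_descriptor(rbind(co10, co10[1, ]), c(z10, 6)),
               "coincident")
})

test_that("RBF kernel evaluates the Gaussian of descriptor distance", {
  m1 <- c(1, 2, 3)
  expect_equal(rbf_kernel(m1, m1, 0.05), 1)
  m2 <- m1 + c(0.05, 0, 0)           # distance exactly sigma
  expect_equal(rbf_kernel(m1, m2, 0.05), exp(-0.5), tolerance = 1e-12)
  expect_equal(exp(-0.5), 0.60653, tolerance = 1e-5)
  expect_equal(rbf_kernel(m1, m2, 0.05), rbf_kernel(m2, m1, 0.05))
  expect_error(rbf_kernel(m1, m2, 0), "sigma")
})

test_that("ridge fit solves the regularized kernel system", {
  # one training point at lambda = 0 interpolates exactly
  d <- matrix(c(0.2, 0.4), 1)
  w <- fit_krr(d, 1.7, sigma = 0.1, lambda_reg = 0)
  expect_equal(as.numeric(w), 1.7)
  # two points with K12 = 0.5 and targets (1, 0): hand-solved 2x2 system
  sigma <- 0.05
  dist12 <- sigma * sqrt(2 * log(2))           # makes K12 = 0.5
  d2 <- rbind(0, dist12)
  w2 <- fit_krr(d2, c(1, 0), sigma = sigma, lambda_reg = 0)
  expect_equal(as.numeric(w2), c(4 / 3, -2 / 3), tolerance = 1e-10)
  # large regularization shrinks weights towards zero
  wbig <- fit_krr(d2, c(1, 0), sigma = sigma, lambda_reg = 1e6)
  expect_lt(max(abs(wbig)), 1e-5)
  # duplicate descriptors at lambda = 0 are singular
  expect_error(fit_krr(rbind(d, d), c(1, 2), 0.1, 0), "lambda_reg")
  # training residuals shrink monotonically as lambda -> 0
  set.seed(12)
  dd <- matrix(stats::runif(30, 0, 0.3), 10, 3)
  f <- sin(rowSums(dd))
  res <- sapply(c(0.1, 0.01, 0.001), function(lam) {
    wl <- fit_krr(dd, f, sigma = 0.2, lambda_reg = lam)
    model <- krr_dipole_model(dd, wl, 0.2, lam, c(1, 2, 3), rep(1, 3), 1, "t")
    max(abs(krr_predict(model, dd) - f))
  })
  expect_true(all(diff(res) < 0))
})

test_that("prediction matches a brute-force kernel sum", {
  set.seed(13)
  Nt <- 20; p <- 5
  dd <- matrix(stats::rnorm(Nt * p), Nt)
  w <- matrix(stats::rnorm(Nt * 2), Nt)
  model <- krr_dipole_model(dd, w, sigma = 0.8, lambda_reg = 0.01,
                            anchors = 1:3, atomic_numbers = rep(1, 3),
                            n_el = 1, target_labels = c("a", "b"))
  x <- stats::rnorm(p)
  brute <- colSums(w * apply(dd, 1, function(r) rbf_kernel(x, r, 0.8)))
  expect_equal(krr_predict(model, x), brute, ignore_attr = TRUE,
               tolerance = 1e-12)
  # far-field prediction decays to zero
  expect_lt(max(abs(krr_predict(model, x + 100))), 1e-10)
})

test_that("analytic prediction gradients pass finite differences and sum rules", {
  set.seed(14)
  co <- generate_geometry(0.9, noise_amplitude = 0.02)
  z <- c(6, 7, 7, 6, rep(1, 6))
  # small model fitted to the backend dipole targets near this geometry
  phis <- seq(0.5, 1.3, length.out = 40)
  dd <- t(sapply(phis, function(p) coulomb_descriptor(generate_geometry(p), z)))
  targ <- sapply(phis, function(p) {
    fr <- model_electronic_frame(the_model(), phi = p)
    fr$dipoles[1, 2, 2]
  })
  w <- fit_krr(dd, targ, sigma = 0.5, lambda_reg = 1e-6)
  model <- krr_dipole_model(dd, w, 0.5, 1e-6, c(2, 3, 1), z, 1, "mu12_y")
  g <- krr_predict_gradient(model, co)
  h <- 1e-5
  for (d in c(1, 8, 17, 29)) {
    at <- (d - 1) %/% 3 + 1; l <- (d - 1) %% 3 + 1
    cp <- co; cm <- co
    cp[at, l] <- cp[at, l] + h; cm[at, l] <- cm[at, l] - h
    fd <- (krr_predict(model, coulomb_descriptor(cp, z)) -
             krr_predict(model, coulomb_descriptor(cm, z))) / (2 * h)
    expect_lt(abs(g[1, d] - as.numeric(fd)), 1e-5)
  }
  gm <- matrix(g[1, ], ncol = 3, byrow = TRUE)
  # translation sum rule: net gradient vanishes
  expect_lt(max(abs(colSums(gm))), 1e-10)
  # rotation sum rule: net torque vanishes
  torque <- colSums(t(sapply(1:10, function(a) polhop:::cross3(co[a, ], gm[a, ]))))
  expect_lt(max(abs(torque)), 1e-8)
})

test_that("body frame is equivariant under rigid rotations", {
  co <- generate_geometry(1.1, noise_amplitude = 0.02, seed = 2)
  anchors <- c(2, 3, 1)
  v <- c(0.3, -0.2, 0.5)
  b0 <- body_frame_transform(co, anchors, v)
  # round trip
  expect_equal(body_frame_transform(co, anchors, b0, inverse = TRUE), v,
               tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:5) {
    R <- polhop:::random_rotation()
    expect_equal(body_frame_transform(t(R %*% t(co)), anchors,
                                      as.numeric(R %*% v)), b0,
                 tolerance = 1e-10)
  }
  # colinear anchors are rejected
  bad <- co; bad[1, ] <- co[2, ] + 2 * (co[3, ] - co[2, ])
  expect_error(body_frame_rotation(bad, anchors), "colinear")
})

test_that("curation keeps small clusters whole and caps large ones", {
  # everything is kept when there are at most n_clusters points
  d <- matrix(stats::rnorm(20), 10, 2)
  expect_equal(curate_training_set(d, n_clusters = 1000), 1:10)
  # two well-separated blobs of 500: exactly 100 from each at cap 100
  set.seed(15)
  blob1 <- matrix(stats::rnorm(1000, sd = 0.05), 500, 2)
  blob2 <- matrix(stats::rnorm(1000, mean = 50, sd = 0.05), 500, 2)
  dd <- rbind(blob1, blob2)
  sel <- curate_training_set(dd, n_clusters = 2, cap = 100, seed = 4)
  expect_length(sel, 200)
  expect_equal(sum(sel <= 500), 100)
  expect_equal(sum(sel > 500), 100)
  # deterministic under a fixed seed
  sel2 <- curate_training_set(dd, n_clusters = 2, cap = 100, seed = 4)
  expect_identical(sel, sel2)
})

test_that("KRR-supplied frame dipoles are symmetric and rotation-consistent", {
  fitted <- fit_dipole_model(the_model(), n_samples = 400,
                             noise_amplitude = 0.001, n_clusters = 400,
                             seed = 9)
  co <- generate_geometry(0.7, noise_amplitude = 0.001, seed = 11)
  kd <- krr_frame_dipoles(fitted$model, co)
  for (l in 1:3) expect_equal(kd$dipoles[, , l], t(kd$dipoles[, , l]))
  fr <- model_electronic_frame(the_model(), coords = co)
  # accuracy at this reduced training size is loose; the production-scale
  # recovery bound lives in the acceptance suite
  expect_lt(max(abs(kd$dipoles - fr$dipoles)), 0.1)
  # lab-frame reconstruction is equivariant under rigid rotation
  set.seed(41)
  R <- polhop:::random_rotation()
  kd_rot <- krr_frame_dipoles(fitted$model, t(R %*% t(co)))
  for (s in 1:2) for (tt in 1:2) {
    expect_equal(as.numeric(R %*% kd$dipoles[s, tt, ]),
                 kd_rot$dipoles[s, tt, ], tolerance = 1e-8)
  }
})
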