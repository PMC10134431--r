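#' Analytic two-state torsional model molecule
#'
#' Closed-form stand-in for an on-the-fly electronic-structure backend: a
#' 10-atom pseudo-azomethane (CH3-N=N-CH3 connectivity) whose two-state
#' electronic structure depends on the CNNC torsion \code{phi} and whose
#' remaining internal motion is governed by a state-independent harmonic
#' scaffold (bond and angle restraints).
#'
#' The diabatic potentials (Hartree; \code{phi} in radians) are
#' \deqn{V_1 = W_1 \sin^2\phi + c_1 \cos\phi, \qquad
#'       V_2 = E_2 - W_2 \sin^2\phi + c_1 \cos\phi, \qquad W_2 = E_2 - W_1,}
#' with constant diabatic coupling \code{Delta}. The gap
#' \code{V_2 - V_1 = E_2 cos^2 phi} closes tangentially at \code{|phi| = 90}
#' degrees, producing a conical-intersection-like funnel with minimum adiabatic
#' gap \code{2 Delta}; the ground surface has a cis well at 0 and a trans well
#' (lower by \code{2 c_1}) at 180 degrees, and the excited surface descends
#' barrierlessly from the cis Franck-Condon point to the funnel. The vertical
#' excitation at cis is \code{sqrt(E_2^2 + 4 Delta^2) ~ E_2}, chosen resonant
#' with a 2.72 eV cavity photon.
#'
#' Diabatic dipoles (atomic units, smooth and even in \code{phi}, components in
#' the lab frame of the template geometry): a transition dipole along Y of 0.8 D
#' at cis decaying to zero at trans, permanent dipoles along Z of the same
#' shape, and small X components growing as \code{sin^2 phi}. The Y-permanent
#' dipoles vanish, so a Y-polarized cavity couples through the transition
#' dipole alone.
#'
#' @param W1 Ground-diabat torsional barrier (Hartree). Default 1.8 eV.
#' @param E2 Diabatic vertical gap at cis (Hartree). Default 2.72 eV.
#' @param c1 Half the trans-cis ground-state energy difference (Hartree).
#'   Default 0.25 eV (trans lower by 0.5 eV).
#' @param delta Constant diabatic coupling (Hartree). Default 0.02 eV.
#' @param trans_dipole_y Cis transition dipole along Y (au). Default 0.8 D.
#' @return Object of class \code{model_molecule}: parameters, template
#'   geometry builder output at \code{phi = 0}, scaffold term lists, masses.
#' @export
model_molecule <- function(W1 = 1.8 * polhop_units$ha_per_ev,
                           E2 = 2.72 * polhop_units$ha_per_ev,
                           c1 = 0.25 * polhop_units$ha_per_ev,
                           delta = 0.02 * polhop_units$ha_per_ev,
                           trans_dipole_y = 0.8 * polhop_units$au_per_debye) {
  stopifnot(E2 > W1, W1 > 0, delta > 0)
  elements <- c("C", "N", "N", "C", rep("H", 6))
  amu <- c(C = 12.011, N = 14.007, H = 1.008)
  masses <- amu[elements] * polhop_units$me_per_amu
  names(masses) <- NULL
  template <- build_template(0)
  scaffold <- scaffold_terms(template)
  structure(
    list(W1 = W1, W2 = E2 - W1, E2 = E2, c1 = c1, delta = delta,
         mu = list(trans_y = trans_dipole_y,  # transition dipole scale, Y
                   perm_z = c(0.40, -0.20),   # permanent Z scales (g, e diabats)
                   perm_x = c(0.10, 0.15)),   # permanent X scales (sin^2 phi)
         elements = elements, masses = masses,
         template = template, scaffold = scaffold,
         dihedral_idx = 1:4),
    class = "model_molecule"
  )
}

# Template pseudo-azomethane geometry (Bohr) at CNNC dihedral phi (radians).
# Atom order: C1 N2 N3 C4 H(C1) x3 H(C4) x3.
build_template <- function(phi) {
  ang <- polhop_units$bohr_per_ang
  r_nn <- 1.25 * ang; r_cn <- 1.47 * ang; r_ch <- 1.09 * ang
  a_cnn <- 112 * pi / 180; a_hcn <- 109.5 * pi / 180
  coords <- matrix(0, 10, 3)
  coords[2, ] <- c(0, 0, 0)                                   # N2
  coords[3, ] <- c(r_nn, 0, 0)                                # N3
  coords[1, ] <- c(r_cn * cos(a_cnn), 0, r_cn * sin(a_cnn))   # C1 (xz-plane)
  coords[4, ] <- place_atom(coords[3, ], coords[2, ], coords[1, ],
                            r_cn, a_cnn, phi)                 # C4: CNNC = phi
  tors_h <- c(60, 180, 300) * pi / 180
  for (k in 1:3) {
    coords[4 + k, ] <- place_atom(coords[1, ], coords[2, ], coords[3, ],
                                  r_ch, a_hcn, tors_h[k])
    coords[7 + k, ] <- place_atom(coords[4, ], coords[3, ], coords[2, ],
                                  r_ch, a_hcn, tors_h[k])
  }
  coords
}

# Harmonic bond/angle restraint lists with equilibrium values measured from a
# reference geometry (so the reference is the exact scaffold minimum). Force
# constants are typical single/double bond and bend stiffnesses.
scaffold_terms <- function(ref) {
  bonds <- rbind(
    c(1, 2), c(2, 3), c(3, 4),
    c(1, 5), c(1, 6), c(1, 7), c(4, 8), c(4, 9), c(4, 10)
  )
  kb <- c(0.35, 0.70, 0.35, rep(0.30, 6))
  r0 <- apply(bonds, 1, function(b) sqrt(sum((ref[b[1], ] - ref[b[2], ])^2)))
  angles <- rbind(
    c(1, 2, 3), c(2, 3, 4),
    c(5, 1, 2), c(6, 1, 2), c(7, 1, 2),
    c(8, 4, 3), c(9, 4, 3), c(10, 4, 3),
    c(5, 1, 6), c(5, 1, 7), c(6, 1, 7),
    c(8, 4, 9), c(8, 4, 10), c(9, 4, 10)
  )
  ka <- rep(0.15, nrow(angles))
  th0 <- apply(angles, 1, function(a) bond_angle(ref, a[1], a[2], a[3]))
  list(bonds = bonds, kb = kb, r0 = r0, angles = angles, ka = ka, th0 = th0)
}

# Scaffold energy and gradient (Hartree, Hartree/Bohr) at coords.
scaffold_energy_gradient <- function(model, coords) {
  sc <- model$scaffold
  e <- 0
  g <- matrix(0, nrow(coords), 3)
  for (b in seq_len(nrow(sc$bonds))) {
    i <- sc$bonds[b, 1]; j <- sc$bonds[b, 2]
    dv <- coords[i, ] - coords[j, ]
    r <- sqrt(sum(dv^2))
    e <- e + 0.5 * sc$kb[b] * (r - sc$r0[b])^2
    gv <- sc$kb[b] * (r - sc$r0[b]) * dv / r
    g[i, ] <- g[i, ] + gv
    g[j, ] <- g[j, ] - gv
  }
  for (a in seq_len(nrow(sc$angles))) {
    i <- sc$angles[a, 1]; j <- sc$angles[a, 2]; k <- sc$angles[a, 3]
    th <- bond_angle(coords, i, j, k)
    pref <- sc$ka[a] * (th - sc$th0[a])
    e <- e + 0.5 * sc$ka[a] * (th - sc$th0[a])^2
    gr <- bond_angle_gradient(coords, i, j, k)
    g[i, ] <- g[i, ] + pref * gr$gi
    g[j, ] <- g[j, ] + pref * gr$gj
    g[k, ] <- g[k, ] + pref * gr$gk
  }
  list(energy = e, gradient = g)
}

# Torsional electronic structure at angle phi: diabats, adiabats, mixing angle
# and their phi-derivatives (all closed form).
model_torsion <- function(model, phi) {
  W1 <- model$W1; W2 <- model$W2; E2 <- model$E2
  c1 <- model$c1; delta <- model$delta
  s2 <- sin(phi)^2
  V1 <- W1 * s2 + c1 * cos(phi)
  V2 <- E2 - W2 * s2 + c1 * cos(phi)
  dV1 <- W1 * sin(2 * phi) - c1 * sin(phi)
  dV2 <- -W2 * sin(2 * phi) - c1 * sin(phi)
  gap <- V2 - V1                       # = E2 cos^2 phi >= 0
  dgap <- dV2 - dV1                    # = -E2 sin 2 phi
  s <- 0.5 * sqrt(gap^2 + 4 * delta^2)
  ds <- gap * dgap / (4 * s)
  m <- (V1 + V2) / 2
  dm <- (dV1 + dV2) / 2
  theta <- 0.5 * atan2(2 * delta, gap)
  dtheta <- -delta * dgap / (gap^2 + 4 * delta^2)
  list(V1 = V1, V2 = V2, dV1 = dV1, dV2 = dV2,
       E = c(m - s, m + s), dE = c(dm - ds, dm + ds),
       theta = theta, dtheta = dtheta)
}

# Diabatic dipole matrices (2 x 2 per lab component) and phi-derivatives.
model_diabatic_dipoles <- function(model, phi) {
  shape <- (1 + cos(phi)) / 2
  dshape <- -sin(phi) / 2
  s2 <- sin(phi)^2
  ds2 <- sin(2 * phi)
  M <- array(0, c(2, 2, 3)); dM <- array(0, c(2, 2, 3))
  # X: small permanent components
  M[1, 1, 1] <- model$mu$perm_x[1] * s2;  dM[1, 1, 1] <- model$mu$perm_x[1] * ds2
  M[2, 2, 1] <- model$mu$perm_x[2] * s2;  dM[2, 2, 1] <- model$mu$perm_x[2] * ds2
  # Y: transition dipole, bright cis -> dark trans
  M[1, 2, 2] <- M[2, 1, 2] <- model$mu$trans_y * shape
  dM[1, 2, 2] <- dM[2, 1, 2] <- model$mu$trans_y * dshape
  # Z: permanent dipoles
  M[1, 1, 3] <- model$mu$perm_z[1] * shape; dM[1, 1, 3] <- model$mu$perm_z[1] * dshape
  M[2, 2, 3] <- model$mu$perm_z[2] * shape; dM[2, 2, 3] <- model$mu$perm_z[2] * dshape
  list(M = M, dM = dM)
}

#' Evaluate the analytic backend at a geometry
#'
#' Returns the full [electronic_frame()] (energies, Cartesian gradients, NAC
#' vectors, lab-frame dipole matrix and its Cartesian gradients) for the model
#' molecule, either at explicit coordinates or at a template geometry with the
#' CNNC torsion set to \code{phi}.
#'
#' @param model A [model_molecule()]; built with defaults when missing.
#' @param coords \code{10 x 3} Cartesian coordinates (Bohr); ignored when
#'   \code{phi} is given.
#' @param phi CNNC dihedral (radians); builds the rigid template at that angle.
#' @return An [electronic_frame()] with two states.
#' @export
#' @examples
#' fr <- model_electronic_frame(phi = pi / 3)
#' fr$energies
model_electronic_frame <- function(model = model_molecule(), coords = NULL,
                                   phi = NULL) {
  if (!is.null(phi)) coords <- build_template(phi)
  if (is.null(coords)) stop("supply coords or phi")
  phi_val <- dihedral_angle(coords, model$dihedral_idx)
  dphi <- dihedral_gradient(coords, model$dihedral_idx)   # N_a x 3
  dphi_flat <- as.numeric(t(dphi))                        # atom-major x,y,z
  tors <- model_torsion(model, phi_val)
  scaf <- scaffold_energy_gradient(model, coords)
  scaf_flat <- as.numeric(t(scaf$gradient))
  ndof <- 3L * nrow(coords)

  energies <- tors$E + scaf$energy
  grads <- rbind(tors$dE[1] * dphi_flat + scaf_flat,
                 tors$dE[2] * dphi_flat + scaf_flat)

  nacs <- array(0, c(2, 2, ndof))
  nacs[1, 2, ] <- -tors$dtheta * dphi_flat     # <g | grad e>
  nacs[2, 1, ] <- tors$dtheta * dphi_flat

  dd <- model_diabatic_dipoles(model, phi_val)
  th <- tors$theta
  G <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # cols: |g>, |e>
  J <- matrix(c(0, 1, -1, 0), 2, 2)                          # dG/dtheta = G J
  dipoles <- array(0, c(2, 2, 3))
  dmu_dphi <- array(0, c(2, 2, 3))
  for (l in 1:3) {
    A <- crossprod(G, dd$M[, , l] %*% G)
    dipoles[, , l] <- (A + t(A)) / 2
    dA <- crossprod(G, dd$dM[, , l] %*% G) +
      tors$dtheta * (A %*% J - J %*% A)
    dmu_dphi[, , l] <- (dA + t(dA)) / 2
  }
  dipole_grads <- array(0, c(2, 2, 3, ndof))
  for (l in 1:3) for (s in 1:2) for (tt in 1:2) {
    dipole_grads[s, tt, l, ] <- dmu_dphi[s, tt, l] * dphi_flat
  }
  electronic_frame(coords, energies, grads, nacs, dipoles, dipole_grads)
}

#' Generate a model geometry at a prescribed torsion
#'
#' Rigid template with the CNNC dihedral set to \code{phi}, plus optional
#' seeded Gaussian Cartesian jitter emulating vibrational spread in a training
#' set.
#'
#' @param phi CNNC dihedral (radians).
#' @param noise_amplitude Standard deviation of the per-coordinate jitter in
#'   Angstrom (default 0: rigid template).
#' @param seed Optional integer seed (local to this call).
#' @return \code{10 x 3} coordinate matrix (Bohr).
#' @export
generate_geometry <- function(phi, noise_amplitude = 0, seed = NULL) {
  stopifnot(noise_amplitude >= 0)
  coords <- build_template(phi)
  if (noise_amplitude > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      on.exit({
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
      })
      set.seed(seed)
    }
    coords <- coords + matrix(stats::rnorm(30, sd = noise_amplitude *
                                             polhop_units$bohr_per_ang), 10, 3)
  }
  coords
}

#' Harmonic Wigner sampling specification from the model minimum
#'
#' Computes the mass-weighted Hessian of the ground-state surface (electronic
#' plus scaffold) at the cis template by central finite differences of the
#' analytic gradient, diagonalizes it and keeps the vibrational modes with
#' frequency above \code{omega_min}. Translations, rotations and the free
#' methyl torsions fall below the cutoff and are excluded from sampling.
#'
#' @param model A [model_molecule()].
#' @param displacement Finite-difference step (Bohr).
#' @param omega_min Frequency floor (Hartree) separating sampled vibrations
#'   from free/zero modes.
#' @return Object of class \code{wigner_spec}: \code{omegas} (Hartree),
#'   \code{modes} (mass-weighted, orthonormal, \code{3N_a x n_modes}),
#'   \code{masses}, \code{ref_coords}.
#' @export
model_wigner_spec <- function(model = model_molecule(), displacement = 1e-3,
                              omega_min = 1e-4) {
  ref <- model$template
  ndof <- 3L * nrow(ref)
  grad_g <- function(coords) {
    fr <- model_electronic_frame(model, coords = coords)
    fr$grads[1, ]
  }
  H <- matrix(0, ndof, ndof)
  for (d in seq_len(ndof)) {
    cp <- ref; cm <- ref
    at <- (d - 1) %/% 3 + 1; xyz <- (d - 1) %% 3 + 1
    cp[at, xyz] <- cp[at, xyz] + displacement
    cm[at, xyz] <- cm[at, xyz] - displacement
    H[, d] <- (grad_g(cp) - grad_g(cm)) / (2 * displacement)
  }
  H <- (H + t(H)) / 2
  m3 <- rep(model$masses, each = 3)
  Hmw <- H / sqrt(outer(m3, m3))
  es <- eigen(Hmw, symmetric = TRUE)
  keep <- es$values > omega_min^2
  omegas <- sqrt(es$values[keep])
  modes <- es$vectors[, keep, drop = FALSE]
  ord <- order(omegas)
  structure(
    list(omegas = omegas[ord], modes = modes[, ord, drop = FALSE],
         masses = model$masses, ref_coords = ref),
    class = "wigner_spec"
  )
}

#' Wigner sampling of initial conditions at T = 0 K
#'
#' Draws positions and momenta from the harmonic ground-state Wigner
#' distribution: per mode, independent Gaussians with
#' \code{Var(R~) = hbar/(2 omega)} and \code{Var(P~) = hbar omega / 2},
#' transformed to Cartesian coordinates through the mass-weighted mode matrix.
#'
#' @param spec A [model_wigner_spec()] (or any list with \code{omegas},
#'   \code{modes}, \code{masses}, \code{ref_coords}).
#' @param n Number of samples, >= 1.
#' @param seed Optional integer seed (local to this call).
#' @return List of \code{n} samples, each with \code{coords} (\code{N_a x 3},
#'   Bohr) and \code{momenta} (length \code{3 N_a}, atomic units, atom-major).
#' @export
wigner_sample <- function(spec, n, seed = NULL) {
  stopifnot(n >= 1)
  if (any(spec$omegas <= 0)) stop("all sampled frequencies must be positive")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  nm <- length(spec$omegas)
  m3 <- rep(spec$masses, each = 3)
  ref_flat <- as.numeric(t(spec$ref_coords))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    q <- stats::rnorm(nm, sd = sqrt(1 / (2 * spec$omegas)))
    p <- stats::rnorm(nm, sd = sqrt(spec$omegas / 2))
    dx <- as.numeric(spec$modes %*% q) / sqrt(m3)
    pp <- as.numeric(spec$modes %*% p) * sqrt(m3)
    out[[k]] <- list(coords = matrix(ref_flat + dx, ncol = 3, byrow = TRUE),
                     momenta = pp)
  }
  out
}
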