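#' Non-adiabatic coupling matrix in the adiabatic-Fock basis
#'
#' Because Fock states carry no nuclear dependence, the derivative coupling in
#' the product basis is block-diagonal in photon number:
#' \code{d_{(gamma,n),(nu,m)} = d_{gamma,nu} delta_{nm}}.
#'
#' @param frame An [electronic_frame()] providing electronic NAC vectors.
#' @param basis An [af_basis()].
#' @return Array \code{size x size x 3N_a}, antisymmetric in the first two
#'   indices for every nuclear degree of freedom.
#' @export
nac_adiabatic_fock <- function(frame, basis) {
  stopifnot(inherits(basis, "af_basis"))
  n_el <- basis$n_el; n_fock <- basis$n_fock
  ndof <- 3L * frame$n_atoms
  K <- basis$size
  d_af <- array(0, c(K, K, ndof))
  Iph <- diag(n_fock)
  for (a in seq_len(ndof)) {
    d_af[, , a] <- kronecker(frame$nacs[seq_len(n_el), seq_len(n_el), a], Iph)
  }
  d_af
}

#' Bare derivative of the polariton potential matrix
#'
#' Assembles \code{dV/dR_a} entry by entry: adiabatic energy gradients on the
#' diagonal blocks, \code{g_c * (eps . grad mu)} on the one-photon coupling
#' entries, and the product-rule derivative of the dipole self-energy block.
#' This is the plain matrix of derivatives of [build_potential_matrix()]; it
#' does not include the non-adiabatic commutator (see
#' [full_gradient_matrix()]).
#'
#' @inheritParams build_potential_matrix
#' @return Array \code{size x size x 3N_a} (Hartree/Bohr); each slice symmetric.
#' @export
grad_potential_matrix <- function(frame, cavity, basis, include_dse = TRUE) {
  stopifnot(inherits(cavity, "cavity_parameters"), inherits(basis, "af_basis"))
  if (is.null(frame$dipole_grads)) {
    stop("frame carries no dipole gradients; evaluate them with the analytic ",
         "backend or a fitted KRR dipole model (krr_frame_dipoles)")
  }
  n_el <- basis$n_el; n_fock <- basis$n_fock
  ndof <- 3L * frame$n_atoms
  K <- basis$size
  emu <- project_dipole(frame, cavity$epsilon)[seq_len(n_el), seq_len(n_el), drop = FALSE]
  a_mat <- fock_annihilation(n_fock)
  x <- a_mat + t(a_mat)
  Iph <- diag(n_fock)
  eps <- cavity$epsilon
  dV <- array(0, c(K, K, ndof))
  for (a in seq_len(ndof)) {
    demu <- eps[1] * frame$dipole_grads[seq_len(n_el), seq_len(n_el), 1, a] +
            eps[2] * frame$dipole_grads[seq_len(n_el), seq_len(n_el), 2, a] +
            eps[3] * frame$dipole_grads[seq_len(n_el), seq_len(n_el), 3, a]
    demu <- matrix(demu, n_el, n_el)
    slice <- kronecker(diag(frame$grads[seq_len(n_el), a], n_el), Iph) +
      cavity$g_c * kronecker(demu, x)
    if (include_dse) {
      ddse <- (cavity$lambda^2 / 2) * (demu %*% emu + emu %*% demu)
      slice <- slice + kronecker(ddse, Iph)
    }
    dV[, , a] <- (slice + t(slice)) / 2
  }
  dV
}

#' Full polariton gradient matrix (energy-conserving form)
#'
#' Completes the bare derivative with the non-adiabatic commutator so that the
#' diagonal of \code{t(U) [gradV] U} is the exact gradient of the polariton
#' eigenvalues (Hellmann-Feynman) and mixed quantum-classical energy is
#' conserved: per nuclear degree of freedom \code{a},
#' \code{[gradV]^a = dV^a + d_af^a V - V d_af^a}.
#'
#' @param dV Array from [grad_potential_matrix()].
#' @param d_af Array from [nac_adiabatic_fock()].
#' @param V Potential matrix from [build_potential_matrix()].
#' @return Array \code{size x size x 3N_a}.
#' @export
full_gradient_matrix <- function(dV, d_af, V) {
  stopifnot(all(dim(dV) == dim(d_af)), nrow(V) == dim(dV)[1])
  out <- dV
  for (a in seq_len(dim(dV)[3])) {
    D <- d_af[, , a]
    out[, , a] <- dV[, , a] + D %*% V - V %*% D
  }
  out
}

#' Nuclear force on the active polariton surface
#'
#' \code{F_a = - sum_ij U_iJ [gradV]^a_ij U_jJ}: the exact (Hellmann-Feynman)
#' force on polariton state \code{J}.
#'
#' @param solution A [diagonalize_potential()] result.
#' @param gradV Array from [full_gradient_matrix()].
#' @param J Active polariton index (1-based).
#' @return Numeric force vector of length \code{3N_a} (Hartree/Bohr).
#' @export
active_force <- function(solution, gradV, J) {
  K <- length(solution$energies)
  if (J < 1 || J > K) stop("active index out of range")
  u <- solution$U[, J]
  ndof <- dim(gradV)[3]
  # contract u' gradV[,,a] u for all a at once
  G <- matrix(gradV, K * K, ndof)
  -as.numeric(crossprod(G, as.numeric(tcrossprod(u))))
}

#' Non-adiabatic coupling between two polariton states
#'
#' Off-diagonal Hellmann-Feynman quotient:
#' \code{d_IK,a = (t(U) [gradV]^a U)_IK / (E_K - E_I)}, antisymmetric under
#' exchange of \code{I} and \code{K}. Used as the velocity-rescaling direction
#' at hops.
#'
#' @inheritParams active_force
#' @param I,K Polariton indices (1-based), \code{I != K}.
#' @param degeneracy_floor Minimum allowed \code{|E_K - E_I|} (Hartree).
#' @return Coupling vector of length \code{3N_a} (1/Bohr).
#' @export
nac_polariton <- function(solution, gradV, I, K, degeneracy_floor = 1e-8) {
  nst <- length(solution$energies)
  if (I == K) stop("I and K must differ")
  if (I < 1 || K < 1 || I > nst || K > nst) stop("index out of range")
  dE <- solution$energies[K] - solution$energies[I]
  if (abs(dE) <= degeneracy_floor) {
    stop("polariton states are degenerate; the NAC direction is undefined - ",
         "rescale along the momentum direction instead")
  }
  uI <- solution$U[, I]; uK <- solution$U[, K]
  ndof <- dim(gradV)[3]
  G <- matrix(gradV, nst * nst, ndof)
  as.numeric(crossprod(G, as.numeric(outer(uI, uK)))) / dE
}
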