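#' Quantum state of the electronic-photonic subsystem
#'
#' Complex Hermitian reduced density matrix in the adiabatic-Fock basis with a
#' time stamp (atomic units). Validated for unit trace, Hermiticity and
#' approximate positivity.
#'
#' @param rho Complex (or real) square matrix.
#' @param time Time in atomic units.
#' @param check Validate invariants (default TRUE).
#' @return Object of class \code{quantum_state}.
#' @export
quantum_state <- function(rho, time = 0, check = TRUE) {
  rho <- as.matrix(rho)
  storage.mode(rho) <- "complex"
  if (check) {
    if (abs(Re(sum(diag(rho))) - 1) > 1e-10 || abs(Im(sum(diag(rho)))) > 1e-10) {
      stop("density trace must be 1 within 1e-10")
    }
    if (max(Mod(rho - Conj(t(rho)))) > 1e-12) stop("density must be Hermitian within 1e-12")
    ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    if (min(Re(ev)) < -1e-10) stop("density must be positive semidefinite within 1e-10")
  }
  structure(list(rho = rho, time = time), class = "quantum_state")
}

#' Cavity-loss jump matrix in the adiabatic-Fock basis
#'
#' \code{L = I_el (x) a} with the photon annihilation operator \code{a |n> =
#' sqrt(n) |n-1>}; for two Fock states this is \code{|0><1|} on each electronic
#' block. The jump operator acts on the photonic degrees of freedom only.
#'
#' @param basis An [af_basis()].
#' @return Real \code{size x size} matrix.
#' @export
jump_matrix <- function(basis) {
  stopifnot(inherits(basis, "af_basis"))
  kronecker(diag(basis$n_el), fock_annihilation(basis$n_fock))
}

# one classical RK4 step of drho/dt = f(rho)
rk4_step <- function(rho, f, dt) {
  k1 <- f(rho)
  k2 <- f(rho + dt / 2 * k1)
  k3 <- f(rho + dt / 2 * k2)
  k4 <- f(rho + dt * k3)
  rho + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' One Runge-Kutta substep of the Hamiltonian/NAC part
#'
#' Fourth-order step of \code{drho/dt = -i [V, rho] - [Rdot.d_af, rho]}
#' (hbar = 1). \code{Rdot.d_af} is the real antisymmetric matrix obtained by
#' contracting the nuclear velocities with the adiabatic-Fock NAC array.
#'
#' @param state A [quantum_state()].
#' @param V Potential matrix (Hartree).
#' @param d_af NAC array (\code{K x K x 3N_a}) or a pre-contracted
#'   \code{K x K} matrix \code{sum_a Rdot_a d_af[, , a]}.
#' @param Rdot Nuclear velocities (length \code{3N_a}); ignored when
#'   \code{d_af} is already contracted.
#' @param dt_sub Substep length (atomic time units).
#' @return Updated [quantum_state()].
#' @export
hamiltonian_substep <- function(state, V, d_af, Rdot, dt_sub) {
  D <- if (length(dim(d_af)) == 3) contract_nac(d_af, Rdot) else d_af
  f <- function(r) -1i * (V %*% r - r %*% V) - (D %*% r - r %*% D)
  rho <- rk4_step(state$rho, f, dt_sub)
  quantum_state(rho, state$time + dt_sub, check = FALSE)
}

# sum_a Rdot[a] * d_af[, , a]
contract_nac <- function(d_af, Rdot) {
  K <- dim(d_af)[1]
  matrix(matrix(d_af, K * K, dim(d_af)[3]) %*% as.numeric(Rdot), K, K)
}

#' One Runge-Kutta substep of the Lindblad loss part
#'
#' Fourth-order step of \code{drho/dt = Gamma (L rho L' - (L'L rho + rho L'L)/2)}.
#' The dissipator is trace-preserving.
#'
#' @param state A [quantum_state()].
#' @param L Jump matrix from [jump_matrix()].
#' @param gamma Loss rate Gamma (atomic units), >= 0.
#' @param dt_sub Substep length (atomic time units).
#' @return Updated [quantum_state()].
#' @export
lindblad_substep <- function(state, L, gamma, dt_sub) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (gamma == 0) {
    return(quantum_state(state$rho, state$time, check = FALSE))
  }
  LtL <- crossprod(L)                        # L real
  f <- function(r) gamma * (L %*% r %*% t(L) - (LtL %*% r + r %*% LtL) / 2)
  rho <- rk4_step(state$rho, f, dt_sub)
  quantum_state(rho, state$time, check = FALSE)
}

#' Split propagation of the reduced density over one nuclear step
#'
#' Performs \code{n_sub} sequential pairs of one Hamiltonian/NAC substep and
#' one Lindblad substep (first-order operator splitting). \code{V}, the
#' contracted NAC matrix and \code{Rdot} are linearly interpolated between the
#' bracketing nuclear steps when the \code{*_old}/\code{*_new} pairs are given;
#' passing a single set of matrices propagates at fixed coefficients.
#'
#' @param state A [quantum_state()].
#' @param V,V_new Potential matrix at the start (and optionally end) of the
#'   nuclear step.
#' @param d_af,d_af_new NAC arrays (or pre-contracted matrices) at the start
#'   (and end).
#' @param Rdot,Rdot_new Velocities at the start (and end); ignored for
#'   pre-contracted NAC matrices.
#' @param L Jump matrix.
#' @param gamma Loss rate.
#' @param dt_nuclear Nuclear step length (atomic time units).
#' @param n_sub Number of quantum substeps per nuclear step (default 100).
#' @return Updated [quantum_state()]; raises an error if the propagation
#'   drifted the trace by more than 1e-8.
#' @export
split_propagate <- function(state, V, d_af, Rdot, L, gamma, dt_nuclear,
                            n_sub = 100L, V_new = NULL, d_af_new = NULL,
                            Rdot_new = NULL) {
  stopifnot(n_sub >= 1)
  dt_sub <- dt_nuclear / n_sub
  D0 <- if (length(dim(d_af)) == 3) contract_nac(d_af, Rdot) else d_af
  D1 <- if (is.null(d_af_new)) D0 else {
    if (length(dim(d_af_new)) == 3) contract_nac(d_af_new, Rdot_new) else d_af_new
  }
  V1 <- if (is.null(V_new)) V else V_new
  interp <- !is.null(V_new) || !is.null(d_af_new)
  st <- state
  for (k in seq_len(n_sub)) {
    if (interp) {
      w <- (k - 0.5) / n_sub                  # midpoint of the substep
      Vk <- (1 - w) * V + w * V1
      Dk <- (1 - w) * D0 + w * D1
    } else {
      Vk <- V; Dk <- D0
    }
    st <- hamiltonian_substep(st, Vk, Dk, NULL, dt_sub)
    st <- lindblad_substep(st, L, gamma, dt_sub)
  }
  drift <- abs(Re(sum(diag(st$rho))) - Re(sum(diag(state$rho))))
  if (drift > 1e-8) {
    stop(sprintf("trace drift %.3e > 1e-8: substeps too coarse for these rates", drift))
  }
  st
}
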