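#' Transform a density matrix from the adiabatic-Fock to the polariton basis
#'
#' \code{rho_pl = t(U) rho_af U}; exactly trace-preserving for orthogonal
#' \code{U}.
#'
#' @param rho_af Density matrix in the adiabatic-Fock basis.
#' @param U Orthogonal eigenvector matrix from [diagonalize_potential()].
#' @return Density matrix in the polariton basis.
#' @export
to_polariton_density <- function(rho_af, U) {
  crossprod(U, rho_af %*% U)
}

#' Global-flux surface-hopping probabilities
#'
#' Partition the polariton states by the sign of their population change over
#' the last propagation interval: states losing population form group A, states
#' gaining form group B. When the active state \code{active} is in A, the
#' probability of switching to a destination \code{J} in B is
#' \deqn{p(I \to J) = \frac{\Delta\rho_{JJ}}{\rho_{II}(t)} \cdot
#'   \frac{-\Delta\rho_{II}}{\sum_{K \in A} (-\Delta\rho_{KK})}}
#' clipped to \code{[0, 1]}. All other switches are forbidden (probability 0).
#'
#' @param rho_pl_prev,rho_pl_now Polariton-basis densities at the start and end
#'   of the interval (trace-normalized).
#' @param active Active polariton index (1-based).
#' @return Numeric vector of destination probabilities (zero at \code{active}).
#' @export
gfsh_probabilities <- function(rho_pl_prev, rho_pl_now, active) {
  p_prev <- Re(diag(rho_pl_prev))
  p_now <- Re(diag(rho_pl_now))
  K <- length(p_prev)
  delta <- p_now - p_prev
  probs <- numeric(K)
  if (delta[active] >= 0) return(probs)      # active state gained: no hops
  rho_ii <- p_prev[active]
  if (rho_ii <= 0) {
    warning("active-state population is zero; switching probabilities set to 0")
    return(probs)
  }
  lossA <- sum(-delta[delta < 0])
  gainers <- which(delta > 0)
  probs[gainers] <- (delta[gainers] / rho_ii) * (-delta[active] / lossA)
  probs[probs < 0] <- 0
  probs[probs > 1] <- 1
  probs
}

#' Stochastic hop decision
#'
#' Cumulative-interval sampling: one uniform draw \code{zeta} is consumed from
#' R's random number stream on every call, so a fixed seed reproduces the whole
#' trajectory regardless of how many hops are accepted.
#'
#' @param probabilities Destination probabilities (>= 0, sum <= 1; larger sums
#'   are renormalized with a warning).
#' @return Destination index, or \code{NA_integer_} for no hop.
#' @export
attempt_hop <- function(probabilities) {
  zeta <- stats::runif(1)
  s <- sum(probabilities)
  if (s > 1 + 1e-12) {
    warning(sprintf("hop probabilities sum to %.3f > 1; clipped", s))
    probabilities <- probabilities / s
  }
  edges <- cumsum(probabilities)
  j <- which(zeta <= edges)[1]
  if (is.na(j) || probabilities[j] <= 0) NA_integer_ else as.integer(j)
}

#' Velocity rescaling at a surface hop
#'
#' Adjusts momenta along the non-adiabatic coupling direction so that kinetic
#' plus potential energy is conserved across the hop: with unit direction
#' \code{u} (the normalized NAC vector), \code{P' = P + kappa * m o u} where
#' \code{kappa} solves \code{sum_a (P_a + kappa m_a u_a)^2 / 2m_a = KE - deltaE}
#' and the real root of smaller magnitude is taken. If the discriminant is
#' negative the hop is frustrated: momenta and active state stay unchanged.
#'
#' @param P Momenta (length \code{3N_a}, atomic units).
#' @param masses Per-atom masses (electron masses), length \code{N_a} or
#'   \code{3N_a}.
#' @param d_IK NAC vector from [nac_polariton()] (any nonzero scale); a zero
#'   vector falls back to the momentum direction with a warning.
#' @param deltaE Energy gap \code{E_new - E_old} (Hartree).
#' @return List with \code{P} (possibly updated), \code{frustrated} (logical)
#'   and \code{kappa}.
#' @export
rescale_velocity <- function(P, masses, d_IK, deltaE) {
  m <- expand_masses(masses, length(P))
  if (!all(is.finite(d_IK))) stop("NAC vector must be finite")
  nrm <- sqrt(sum(d_IK^2))
  if (nrm < 1e-14) {
    warning("zero NAC vector; rescaling along the momentum direction")
    d_IK <- P
    nrm <- sqrt(sum(d_IK^2))
    if (nrm < 1e-14) return(list(P = P, frustrated = TRUE, kappa = NA_real_))
  }
  u <- d_IK / nrm
  a <- sum(m * u^2) / 2
  b <- sum(u * P)
  cc <- deltaE
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(list(P = P, frustrated = TRUE, kappa = NA_real_))
  r1 <- (-b + sqrt(disc)) / (2 * a)
  r2 <- (-b - sqrt(disc)) / (2 * a)
  kappa <- if (abs(r1) <= abs(r2)) r1 else r2
  list(P = P + kappa * m * u, frustrated = FALSE, kappa = kappa)
}

expand_masses <- function(masses, ndof) {
  if (length(masses) == ndof) return(as.numeric(masses))
  if (3L * length(masses) == ndof) return(rep(as.numeric(masses), each = 3L))
  stop("masses must have length N_a or 3N_a")
}

#' Loss-induced hop channel (no velocity rescaling)
#'
#' Applies the GFSH partition to the density change produced by the Lindblad
#' (cavity-loss) part of the propagation. Because the lost energy leaves
#' through the cavity mirror, accepted hops change the active state without
#' touching the nuclear momenta; the energy difference is returned as
#' dissipated energy for bookkeeping.
#'
#' @param rho_pl_before_loss,rho_pl_after_loss Polariton densities before and
#'   after the loss substeps.
#' @param active Active polariton index.
#' @param energies Polariton energies (for the dissipation record).
#' @return List with \code{active} (possibly new), \code{hopped} (logical) and
#'   \code{dissipated} (Hartree, 0 when no hop).
#' @export
loss_hop_channel <- function(rho_pl_before_loss, rho_pl_after_loss, active,
                             energies) {
  probs <- gfsh_probabilities(rho_pl_before_loss, rho_pl_after_loss, active)
  dest <- attempt_hop(probs)
  if (is.na(dest)) {
    list(active = active, hopped = FALSE, dissipated = 0)
  } else {
    list(active = as.integer(dest), hopped = TRUE,
         dissipated = energies[active] - energies[dest])
  }
}

#' Energy-based decoherence correction
#'
#' Damps the amplitude of every non-active polariton state \code{J} by
#' \code{exp(-dt / tau_J)} with
#' \code{tau_J = (hbar / |E_J - E_I|) (1 + alpha / E_kin)} and rescales the
#' active-state population so the trace stays 1. Applied to a density matrix:
#' populations scale by the squared amplitude factor and coherences by the
#' product of the two amplitude factors, with the active-state factor set by
#' the trace constraint.
#'
#' @param rho_pl Polariton-basis density matrix.
#' @param active Active polariton index \code{I}.
#' @param energies Polariton energies (Hartree).
#' @param Ekin Nuclear kinetic energy (Hartree), > 0.
#' @param dt Nuclear time step (atomic units).
#' @param alpha Decoherence parameter (Hartree), default 0.1.
#' @return Damped, trace-1 density matrix.
#' @export
decoherence_correction <- function(rho_pl, active, energies, Ekin, dt,
                                   alpha = 0.1) {
  if (Ekin <= 0) stop("Ekin must be > 0")
  K <- length(energies)
  f <- numeric(K)
  for (J in seq_len(K)) {
    if (J == active) next
    gap <- abs(energies[J] - energies[active])
    if (gap < 1e-14) { f[J] <- 1; next }     # degenerate: tau -> Inf
    tau <- (1 / gap) * (1 + alpha / Ekin)
    f[J] <- exp(-dt / tau)
  }
  pII <- Re(rho_pl[active, active])
  others <- sum(Re(diag(rho_pl))[-active] * f[-active]^2)
  f[active] <- if (pII > 1e-14) sqrt(max(0, 1 - others) / pII) else 1
  rho <- rho_pl * outer(f, f)
  # restore exact trace against rounding
  tr <- Re(sum(diag(rho)))
  if (tr > 1e-14) rho <- rho / tr
  rho
}
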