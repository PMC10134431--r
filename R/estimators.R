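#' Mixed estimator density in the polariton basis
#'
#' Combines the active-state indicator on the diagonal with coherences built
#' from the quantum amplitudes: \code{rho_II = delta(I, active)} on the
#' diagonal and \code{c_I c_J*} off the diagonal. Accepts either the amplitude
#' vector or a full polariton density (whose off-diagonals are then reused).
#'
#' @param coeffs Complex amplitude vector with \code{sum |c|^2 = 1}, or a
#'   polariton-basis density matrix.
#' @param active Active polariton index.
#' @return Complex density matrix with unit trace.
#' @export
mixed_estimator_density <- function(coeffs, active) {
  if (is.matrix(coeffs)) {
    rho <- coeffs
    K <- nrow(rho)
  } else {
    if (abs(sum(Mod(coeffs)^2) - 1) > 1e-8) stop("amplitudes must be normalized")
    rho <- outer(coeffs, Conj(coeffs))
    K <- length(coeffs)
  }
  out <- rho
  diag(out) <- 0
  out[active, active] <- 1
  out
}

#' Ensemble record
#'
#' Collects per-trajectory time series on a shared time grid for the ensemble
#' estimators. Normally produced by [run_ensemble()].
#'
#' @param trajectories List of trajectory records from [run_trajectory()].
#' @return Object of class \code{ensemble_record}.
#' @export
ensemble_record <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  t0 <- trajectories[[1]]$time
  for (tr in trajectories) {
    if (length(tr$time) != length(t0) || max(abs(tr$time - t0)) > 1e-9) {
      stop("all trajectories must share the same time grid")
    }
  }
  structure(list(trajectories = trajectories, time = t0,
                 n = length(trajectories)),
            class = "ensemble_record")
}

#' @export
print.ensemble_record <- function(x, ...) {
  cat(sprintf("ensemble: %d trajectories, %d steps, t_final = %.1f fs\n",
              x$n, length(x$time) - 1,
              max(x$time) / polhop_units$au_per_fs))
  invisible(x)
}

#' Adiabatic-Fock populations (mixed estimator, trajectory average)
#'
#' Averages \code{diag(U rho_pl t(U))} over trajectories, with \code{rho_pl}
#' the mixed-estimator polariton density recorded at each step.
#'
#' @param ensemble An [ensemble_record()].
#' @return Matrix \code{(n_steps+1) x K} of populations; rows sum to 1.
#' @export
adiabatic_fock_population <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_record"))
  acc <- 0
  for (tr in ensemble$trajectories) acc <- acc + tr$pop_af
  acc / ensemble$n
}

#' Polariton populations (active-state estimator)
#'
#' Fraction of trajectories whose active state is \code{J} at each time.
#'
#' @param ensemble An [ensemble_record()].
#' @return Matrix \code{(n_steps+1) x K}; rows sum to 1.
#' @export
polariton_population <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_record"))
  K <- ncol(ensemble$trajectories[[1]]$pop_af)
  nt <- length(ensemble$time)
  out <- matrix(0, nt, K)
  for (tr in ensemble$trajectories) {
    out[cbind(seq_len(nt), tr$active)] <- out[cbind(seq_len(nt), tr$active)] + 1
  }
  out / ensemble$n
}

#' Trans-isomer fraction
#'
#' Fraction of trajectories beyond the dividing surface:
#' \code{mean(Theta(|phi| - |phi0|))} with the signed dihedral \code{phi} in
#' \code{(-180, 180]} degrees and the boundary counted as trans
#' (\code{Theta(0) = 1}).
#'
#' @param ensemble An [ensemble_record()] whose trajectories carry a
#'   \code{dihedral} series (radians).
#' @param phi0 Dividing surface in degrees (default 90).
#' @return Numeric vector over the time grid, values in \code{[0, 1]}.
#' @export
trans_fraction <- function(ensemble, phi0 = 90) {
  stopifnot(inherits(ensemble, "ensemble_record"))
  thr <- abs(phi0) * pi / 180
  acc <- 0
  for (tr in ensemble$trajectories) {
    phi <- atan2(sin(tr$dihedral), cos(tr$dihedral))  # wrap to (-pi, pi]
    acc <- acc + as.numeric(abs(phi) >= thr)
  }
  acc / ensemble$n
}

#' Dipole-gauge photon number operator in the adiabatic-Fock basis
#'
#' The bare \code{a'a} is not the physical photon number in the dipole gauge;
#' the gauge-corrected (PZW-displaced) operator is
#' \code{N = (a' + g)(a + g)} with the electronic displacement
#' \code{g = lambda (eps.mu) / sqrt(2 omega_c) = (g_c/omega_c) (eps.mu)},
#' truncated to the retained electronic states. The operator is positive
#' semidefinite by construction.
#'
#' @param frame An [electronic_frame()].
#' @param cavity A [cavity_parameters()].
#' @param basis An [af_basis()].
#' @return Real symmetric matrix \code{size x size}.
#' @export
photon_number_operator <- function(frame, cavity, basis) {
  n_el <- basis$n_el; n_fock <- basis$n_fock
  emu <- project_dipole(frame, cavity$epsilon)[seq_len(n_el), seq_len(n_el), drop = FALSE]
  g <- (cavity$g_c / cavity$omega_c) * emu
  a <- fock_annihilation(n_fock)
  Iph <- diag(n_fock); Iel <- diag(n_el)
  # (a' + g)(a + g) = a'a + g a + a' g + g^2, with g acting on electrons only
  kronecker(Iel, crossprod(a)) +
    kronecker(g, a + t(a)) +
    kronecker(g %*% g, Iph)
}

#' Expected photon number
#'
#' \code{<N> = Re Tr[rho N]} with the gauge-corrected operator from
#' [photon_number_operator()].
#'
#' @param rho_af Density matrix in the adiabatic-Fock basis.
#' @inheritParams photon_number_operator
#' @return Non-negative scalar.
#' @export
photon_number <- function(rho_af, frame, cavity, basis) {
  N <- photon_number_operator(frame, cavity, basis)
  Re(sum(diag(rho_af %*% N)))
}
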