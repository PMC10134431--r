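#' Cavity parameters
#'
#' Bundles the single-mode cavity description: photon energy, light-matter
#' coupling strength, polarization direction, Fock-space truncation and loss
#' rate. The coupling convention is \code{g_c = lambda * sqrt(hbar*omega_c/2)},
#' so the single-photon coupling matrix element is \code{g_c * (eps.mu)} and the
#' dipole self-energy prefactor is \code{lambda^2/2} with
#' \code{lambda = g_c * sqrt(2/omega_c)}.
#'
#' @param omega_c Photon energy \code{hbar*omega_c} in Hartree; must be > 0.
#' @param g_c Coupling strength in atomic units; must be >= 0.
#' @param epsilon Unit polarization vector (x, y, z); checked to norm 1 within
#'   1e-12.
#' @param n_fock Number of Fock states retained (\code{|0> ... |n_fock-1>});
#'   must be >= 2. Default 3.
#' @param gamma Cavity loss rate Gamma in atomic units (energy, hbar = 1);
#'   must be >= 0.
#' @return An object of class \code{cavity_parameters}.
#' @export
#' @examples
#' cav <- cavity_parameters(omega_c = 2.72 * polhop_units$ha_per_ev,
#'                          g_c = 0.005, epsilon = c(0, 1, 0))
cavity_parameters <- function(omega_c, g_c, epsilon, n_fock = 3L, gamma = 0) {
  epsilon <- as.numeric(epsilon)
  if (length(epsilon) != 3 || abs(sqrt(sum(epsilon^2)) - 1) > 1e-12) {
    stop("epsilon must be a unit 3-vector (norm 1 within 1e-12)")
  }
  if (!is.numeric(omega_c) || omega_c <= 0) stop("omega_c must be > 0")
  if (g_c < 0) stop("g_c must be >= 0")
  if (gamma < 0) stop("gamma must be >= 0")
  n_fock <- as.integer(n_fock)
  if (n_fock < 2) stop("n_fock must be >= 2")
  structure(
    list(omega_c = omega_c, g_c = g_c, epsilon = epsilon,
         n_fock = n_fock, gamma = gamma,
         lambda = g_c * sqrt(2 / omega_c)),
    class = "cavity_parameters"
  )
}

#' Adiabatic-Fock basis
#'
#' Product basis \code{|electronic adiabatic state alpha> (x) |photon number n>}
#' with electronic-major ordering: linear index \code{i = (alpha-1)*n_fock + n + 1}
#' for \code{alpha = 1..n_el} and \code{n = 0..n_fock-1}.
#'
#' @param n_el Number of electronic states.
#' @param n_fock Fock cutoff.
#' @return An object of class \code{af_basis} with the index map as a
#'   data frame (\code{index}, \code{el}, \code{n}).
#' @export
af_basis <- function(n_el, n_fock) {
  n_el <- as.integer(n_el); n_fock <- as.integer(n_fock)
  stopifnot(n_el >= 1, n_fock >= 2)
  el <- rep(seq_len(n_el), each = n_fock)
  n  <- rep(seq_len(n_fock) - 1L, times = n_el)
  structure(
    list(n_el = n_el, n_fock = n_fock, size = n_el * n_fock,
         index_map = data.frame(index = seq_len(n_el * n_fock), el = el, n = n)),
    class = "af_basis"
  )
}

#' Linear index of an adiabatic-Fock state
#'
#' @param basis An [af_basis()].
#' @param el Electronic state (1-based).
#' @param n Photon number (0-based).
#' @return Integer linear index.
#' @export
af_index <- function(basis, el, n) {
  stopifnot(inherits(basis, "af_basis"))
  if (any(el < 1 | el > basis$n_el) || any(n < 0 | n > basis$n_fock - 1)) {
    stop("state label outside the basis")
  }
  as.integer((el - 1L) * basis$n_fock + n + 1L)
}

#' @export
print.cavity_parameters <- function(x, ...) {
  cat(sprintf(
    "cavity: hbar*omega_c = %.6f Ha (%.3f eV), g_c = %.4g au, eps = (%g, %g, %g), n_fock = %d, Gamma = %.3g Ha\n",
    x$omega_c, x$omega_c * polhop_units$ev_per_ha, x$g_c,
    x$epsilon[1], x$epsilon[2], x$epsilon[3], x$n_fock, x$gamma))
  invisible(x)
}

#' @export
print.af_basis <- function(x, ...) {
  cat(sprintf("adiabatic-Fock basis: %d electronic x %d Fock = %d states (electronic-major)\n",
              x$n_el, x$n_fock, x$size))
  invisible(x)
}
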