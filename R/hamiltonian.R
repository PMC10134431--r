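#' Project the dipole matrix onto the cavity polarization
#'
#' Returns the electronic matrix \code{(eps.mu)_{gamma,nu} = eps_x mu^x + eps_y
#' mu^y + eps_z mu^z} used in the light-matter coupling and the dipole
#' self-energy.
#'
#' @param frame An [electronic_frame()] (or any list carrying a
#'   \code{dipoles} array \code{N_el x N_el x 3}).
#' @param epsilon Unit polarization vector.
#' @return Symmetric \code{N_el x N_el} matrix in atomic units.
#' @export
project_dipole <- function(frame, epsilon) {
  epsilon <- as.numeric(epsilon)
  if (length(epsilon) != 3 || abs(sqrt(sum(epsilon^2)) - 1) > 1e-12) {
    stop("epsilon must be a unit 3-vector")
  }
  d <- frame$dipoles
  n <- dim(d)[1]
  matrix(epsilon[1] * d[, , 1] + epsilon[2] * d[, , 2] + epsilon[3] * d[, , 3],
         n, n)
}

# Photon ladder matrices in the truncated Fock space: a |n> = sqrt(n) |n-1>.
fock_annihilation <- function(n_fock) {
  a <- matrix(0, n_fock, n_fock)
  if (n_fock > 1) {
    for (n in 2:n_fock) a[n - 1, n] <- sqrt(n - 1)
  }
  a
}

#' Build the Pauli-Fierz potential matrix in the adiabatic-Fock basis
#'
#' Assembles the Hermitian (real symmetric) polariton potential
#' \deqn{V_{(nu,n),(gamma,m)} = [E_nu + omega_c (n + 1/2)] \delta_{gamma nu}
#'  \delta_{nm} + g_c (eps.mu)_{gamma nu} (\sqrt{m+1}\,\delta_{n,m+1} +
#'  \sqrt{m}\,\delta_{n,m-1}) + (lambda^2/2) D^2_{gamma nu} \delta_{nm}}
#' where \code{D^2 = (eps.mu)^2} is the dipole self-energy block with the dipole
#' operator truncated to the retained electronic states (matter truncation), and
#' \code{lambda = g_c sqrt(2/omega_c)}.
#'
#' @param frame An [electronic_frame()] with at least \code{basis$n_el} states.
#' @param cavity A [cavity_parameters()].
#' @param basis An [af_basis()].
#' @param include_dse Include the dipole self-energy block (default TRUE).
#'   Disabling it isolates the linear (Rabi) coupling, e.g. for the two-level
#'   splitting check.
#' @return Symmetric \code{basis$size x basis$size} matrix (Hartree).
#' @export
#' @examples
#' frame <- model_electronic_frame(phi = 0.3)
#' cav <- cavity_parameters(0.09995, 0.005, c(0, 1, 0))
#' V <- build_potential_matrix(frame, cav, af_basis(2, cav$n_fock))
build_potential_matrix <- function(frame, cavity, basis, include_dse = TRUE) {
  stopifnot(inherits(cavity, "cavity_parameters"), inherits(basis, "af_basis"))
  if (frame$n_el < basis$n_el) stop("frame has fewer electronic states than the basis")
  n_el <- basis$n_el; n_fock <- basis$n_fock
  emu <- project_dipole(frame, cavity$epsilon)[seq_len(n_el), seq_len(n_el), drop = FALSE]
  a <- fock_annihilation(n_fock)
  x <- a + t(a)                                  # sqrt(m+1) and sqrt(m) ladder part
  diag_ph <- diag(cavity$omega_c * (0:(n_fock - 1) + 0.5), n_fock)
  Eel <- diag(frame$energies[seq_len(n_el)], n_el)
  Iel <- diag(n_el); Iph <- diag(n_fock)
  # electronic-major ordering matches kronecker(el, fock)
  V <- kronecker(Eel, Iph) + kronecker(Iel, diag_ph) +
    cavity$g_c * kronecker(emu, x)
  if (include_dse) {
    dse <- (cavity$lambda^2 / 2) * (emu %*% emu)
    V <- V + kronecker(dse, Iph)
  }
  (V + t(V)) / 2
}

#' Diagonalize a polariton potential matrix with phase continuity
#'
#' Solves the polariton eigenproblem and returns eigenvalues in ascending order
#' with a deterministic eigenvector phase convention. If \code{prev_U} is given,
#' each new column is matched to a previous column by maximal absolute overlap
#' (greedy over decreasing overlap magnitude) and its sign is chosen so that the
#' matched overlap is positive; this prevents spurious sign flips of forces and
#' couplings along a trajectory. Without \code{prev_U}, the largest-magnitude
#' component of each column is made positive.
#'
#' @param V Real symmetric potential matrix (validated to 1e-10).
#' @param prev_U Optional orthogonal matrix of the previous step's eigenvectors.
#' @return An object of class \code{polariton_solution}: list with \code{V},
#'   \code{U} (columns are polariton states), \code{energies} (ascending) and,
#'   when \code{prev_U} is supplied, \code{match} where \code{match[j]} is the
#'   previous column that new column \code{j} continues.
#' @export
diagonalize_potential <- function(V, prev_U = NULL) {
  if (max(abs(V - t(V))) > 1e-10) stop("V must be symmetric within 1e-10")
  es <- eigen((V + t(V)) / 2, symmetric = TRUE)
  ord <- order(es$values)
  energies <- es$values[ord]
  U <- es$vectors[, ord, drop = FALSE]
  K <- ncol(U)
  match_vec <- NULL
  if (!is.null(prev_U)) {
    O <- crossprod(prev_U, U)            # O[i, j] = <prev_i | new_j>
    match_vec <- integer(K)
    absO <- abs(O)
    for (step in seq_len(K)) {           # greedy over decreasing overlap
      idx <- arrayInd(which.max(absO), dim(absO))
      i <- idx[1]; j <- idx[2]
      match_vec[j] <- i
      if (O[i, j] < 0) U[, j] <- -U[, j]
      absO[i, ] <- -Inf; absO[, j] <- -Inf
    }
  } else {
    for (j in seq_len(K)) {
      i <- which.max(abs(U[, j]))
      if (U[i, j] < 0) U[, j] <- -U[, j]
    }
  }
  structure(
    list(V = V, U = U, energies = energies, match = match_vec),
    class = "polariton_solution"
  )
}

#' @export
print.polariton_solution <- function(x, ...) {
  cat(sprintf("polariton solution: %d states, E = %s Ha\n",
              length(x$energies),
              paste(sprintf("%.6f", x$energies), collapse = ", ")))
  invisible(x)
}
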