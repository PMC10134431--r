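#' Electronic-structure data at one geometry
#'
#' Container for every matter quantity the polariton Hamiltonian needs at a
#' single nuclear configuration: adiabatic energies, their Cartesian gradients,
#' non-adiabatic coupling vectors, the dipole matrix and its Cartesian
#' gradients. In an on-the-fly calculation these come from an electronic
#' structure backend; here they are usually supplied by [model_electronic_frame()]
#' or, for the dipole blocks, by a fitted [krr_dipole_model()].
#'
#' @param coords \code{N_a x 3} nuclear positions (Bohr).
#' @param energies Length-\code{N_el} adiabatic energies (Hartree).
#' @param grads \code{N_el x (3 N_a)} energy gradients (Hartree/Bohr), each row
#'   the flattened (atom-major: x1,y1,z1,x2,...) gradient of one state.
#' @param nacs \code{N_el x N_el x (3 N_a)} array of derivative couplings
#'   d_{gamma,nu} (1/Bohr); antisymmetric in the first two indices.
#' @param dipoles \code{N_el x N_el x 3} dipole matrix (atomic units, e*Bohr);
#'   symmetric in the first two indices; last index is the lab component x,y,z.
#' @param dipole_grads Optional \code{N_el x N_el x 3 x (3 N_a)} array of
#'   Cartesian dipole gradients; \code{NULL} when unavailable (then operations
#'   that need them raise an informative error).
#' @return An object of class \code{electronic_frame}.
#' @export
electronic_frame <- function(coords, energies, grads, nacs, dipoles,
                             dipole_grads = NULL) {
  coords <- as.matrix(coords)
  n_a <- nrow(coords)
  n_el <- length(energies)
  ndof <- 3L * n_a
  stopifnot(ncol(coords) == 3)
  if (!is.matrix(grads) || !all(dim(grads) == c(n_el, ndof))) {
    stop("grads must be N_el x 3N_a")
  }
  if (!all(dim(nacs) == c(n_el, n_el, ndof))) stop("nacs must be N_el x N_el x 3N_a")
  if (!all(dim(dipoles) == c(n_el, n_el, 3))) stop("dipoles must be N_el x N_el x 3")
  for (l in 1:3) {
    if (max(abs(dipoles[, , l] - t(dipoles[, , l]))) > 1e-10) {
      stop("dipole matrix must be symmetric in the state indices")
    }
  }
  asym <- max(abs(nacs + aperm(nacs, c(2, 1, 3))))
  if (asym > 1e-10) stop("NAC array must be antisymmetric in the state indices")
  if (!is.null(dipole_grads) &&
      !all(dim(dipole_grads) == c(n_el, n_el, 3, ndof))) {
    stop("dipole_grads must be N_el x N_el x 3 x 3N_a")
  }
  structure(
    list(coords = coords, energies = as.numeric(energies), grads = grads,
         nacs = nacs, dipoles = dipoles, dipole_grads = dipole_grads,
         n_el = n_el, n_atoms = n_a),
    class = "electronic_frame"
  )
}

#' @export
print.electronic_frame <- function(x, ...) {
  cat(sprintf("electronic frame: %d atoms, %d states, E = %s Ha%s\n",
              x$n_atoms, x$n_el,
              paste(sprintf("%.6f", x$energies), collapse = ", "),
              if (is.null(x$dipole_grads)) " (no dipole gradients)" else ""))
  invisible(x)
}

#' Serialize an electronic frame to a columnar data frame
#'
#' Flat keyed representation (one row per scalar entry) suitable for writing
#' with \code{write.csv} and re-reading with [frame_from_table()].
#'
#' @param frame An [electronic_frame()].
#' @return A data frame with columns \code{field, i, j, k, dof, value}.
#' @export
frame_to_table <- function(frame) {
  stopifnot(inherits(frame, "electronic_frame"))
  rows <- list()
  add <- function(field, value, i = NA, j = NA, k = NA, dof = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      field = field, i = i, j = j, k = k, dof = dof, value = value)
  }
  for (a in seq_len(frame$n_atoms)) for (l in 1:3) {
    add("coords", frame$coords[a, l], i = a, k = l)
  }
  for (s in seq_len(frame$n_el)) add("energies", frame$energies[s], i = s)
  for (s in seq_len(frame$n_el)) for (d in seq_len(3 * frame$n_atoms)) {
    add("grads", frame$grads[s, d], i = s, dof = d)
  }
  for (s in seq_len(frame$n_el)) for (t in seq_len(frame$n_el)) {
    for (d in seq_len(3 * frame$n_atoms)) {
      add("nacs", frame$nacs[s, t, d], i = s, j = t, dof = d)
    }
    for (l in 1:3) add("dipoles", frame$dipoles[s, t, l], i = s, j = t, k = l)
  }
  if (!is.null(frame$dipole_grads)) {
    for (s in seq_len(frame$n_el)) for (t in seq_len(frame$n_el)) {
      for (l in 1:3) for (d in seq_len(3 * frame$n_atoms)) {
        add("dipole_grads", frame$dipole_grads[s, t, l, d],
            i = s, j = t, k = l, dof = d)
      }
    }
  }
  do.call(rbind, rows)
}

#' Rebuild an electronic frame from its columnar form
#'
#' Inverse of [frame_to_table()].
#'
#' @param tab Data frame produced by [frame_to_table()].
#' @return An [electronic_frame()].
#' @export
frame_from_table <- function(tab) {
  n_a <- max(tab$i[tab$field == "coords"])
  n_el <- max(tab$i[tab$field == "energies"])
  ndof <- 3L * n_a
  coords <- matrix(0, n_a, 3)
  cc <- tab[tab$field == "coords", ]
  coords[cbind(cc$i, cc$k)] <- cc$value
  en <- tab[tab$field == "energies", ]
  energies <- numeric(n_el); energies[en$i] <- en$value
  grads <- matrix(0, n_el, ndof)
  gg <- tab[tab$field == "grads", ]
  grads[cbind(gg$i, gg$dof)] <- gg$value
  nacs <- array(0, c(n_el, n_el, ndof))
  nn <- tab[tab$field == "nacs", ]
  nacs[cbind(nn$i, nn$j, nn$dof)] <- nn$value
  dipoles <- array(0, c(n_el, n_el, 3))
  dd <- tab[tab$field == "dipoles", ]
  dipoles[cbind(dd$i, dd$j, dd$k)] <- dd$value
  dipole_grads <- NULL
  dg <- tab[tab$field == "dipole_grads", ]
  if (nrow(dg) > 0) {
    dipole_grads <- array(0, c(n_el, n_el, 3, ndof))
    dipole_grads[cbind(dg$i, dg$j, dg$k, dg$dof)] <- dg$value
  }
  electronic_frame(coords, energies, grads, nacs, dipoles, dipole_grads)
}
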