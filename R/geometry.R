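#' Signed dihedral angle of four atoms
#'
#' Computes the IUPAC right-handed signed dihedral defined by atoms
#' \code{idx[1]-idx[2]-idx[3]-idx[4]}, in radians in \code{(-pi, pi]}.
#'
#' @param coords Numeric matrix \code{N_a x 3} of Cartesian positions (any
#'   consistent length unit).
#' @param idx Integer vector of four atom indices.
#' @return Signed dihedral angle in radians.
#' @export
dihedral_angle <- function(coords, idx = 1:4) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, length(idx) == 4)
  b1 <- coords[idx[2], ] - coords[idx[1], ]
  b2 <- coords[idx[3], ] - coords[idx[2], ]
  b3 <- coords[idx[4], ] - coords[idx[3], ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("dihedral undefined: three of the four atoms are colinear")
  }
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2n)
  atan2(y, x)
}

#' Analytic Cartesian gradient of a dihedral angle
#'
#' Standard gradient of the signed torsion with respect to the positions of its
#' four defining atoms (Blondel & Karplus form); all other atoms get zero.
#'
#' @inheritParams dihedral_angle
#' @return Numeric matrix \code{N_a x 3}: \code{d phi / d r}.
#' @export
dihedral_gradient <- function(coords, idx = 1:4) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, length(idx) == 4)
  b1 <- coords[idx[2], ] - coords[idx[1], ]
  b2 <- coords[idx[3], ] - coords[idx[2], ]
  b3 <- coords[idx[4], ] - coords[idx[3], ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  n1sq <- sum(n1^2); n2sq <- sum(n2^2)
  if (n1sq < 1e-20 || n2sq < 1e-20) {
    stop("dihedral gradient undefined: colinear atoms")
  }
  b2len <- sqrt(sum(b2^2))
  g <- matrix(0, nrow(coords), 3)
  gA <- -b2len / n1sq * n1
  gD <-  b2len / n2sq * n2
  f1 <- sum(b1 * b2) / sum(b2^2)
  f2 <- sum(b3 * b2) / sum(b2^2)
  gB <- -(1 + f1) * gA + f2 * gD
  gC <- -(gA + gB + gD)
  g[idx[1], ] <- gA
  g[idx[2], ] <- gB
  g[idx[3], ] <- gC
  g[idx[4], ] <- gD
  g
}

# 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# bond angle a-b-c in radians
bond_angle <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  acos(max(-1, min(1, sum(u * v) / (cu * cv))))
}

# Gradient of the bond angle i-j-k with respect to the three atom positions.
# Returns list(gi, gj, gk).
bond_angle_gradient <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
  cth <- max(-1, min(1, sum(u * v) / (lu * lv)))
  sth <- sqrt(max(1e-14, 1 - cth^2))
  gi <- (cth * u / lu - v / lv) / (lu * sth)
  gk <- (cth * v / lv - u / lu) / (lv * sth)
  gj <- -(gi + gk)
  list(gi = gi, gj = gj, gk = gk)
}

# Place an atom from internal coordinates (NeRF construction): returns the
# position of a new atom at distance `bond` from a, angle `angle` (radians)
# new-a-b, and dihedral `tors` new-a-b-c.
place_atom <- function(a, b, c, bond, angle, tors) {
  bc <- a - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - c, bc)
  if (sum(n^2) < 1e-20) stop("place_atom: reference atoms colinear")
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(angle), bond * sin(angle) * cos(tors),
          bond * sin(angle) * sin(tors))
  a + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Random proper rotation matrix (uniform over SO(3)) from a supplied generator
# state; used by property tests.
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Read an XYZ file
#'
#' Standard multi-frame XYZ: atom count line, comment line, then element and
#' three Cartesian coordinates in Angstrom per atom. Coordinates are converted
#' to Bohr.
#'
#' @param path Path to an XYZ file.
#' @return A list of frames; each frame is a list with \code{elements}
#'   (character vector) and \code{coords} (\code{N_a x 3} matrix, Bohr).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    block <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(block), "\\s+")
    el <- vapply(toks, `[`, character(1), 1)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- list(
      elements = el,
      coords = xyz * polhop_units$bohr_per_ang
    )
    i <- i + 2 + n
  }
  frames
}

#' Write geometries to an XYZ file
#'
#' @param frames A single frame (list with \code{elements}, \code{coords} in
#'   Bohr) or a list of such frames.
#' @param path Output path.
#' @param comments Optional character vector of per-frame comment lines.
#' @return Invisibly, \code{path}.
#' @export
write_xyz <- function(frames, path, comments = NULL) {
  if (!is.null(frames$coords)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    cmt <- if (is.null(comments)) "" else comments[[k]]
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(cmt, con)
    xyz <- fr$coords * polhop_units$ang_per_bohr
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f",
                       fr$elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
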