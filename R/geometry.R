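#' Host geometry: cavity atoms and (optionally) charged interaction sites
#'
#' Container for the host structure used by the reaction coordinate, the
#' solvation analyses and the pair-energy profiler.  `atoms` holds every
#' atom with coordinates plus per-atom charge and van der Waals parameters;
#' `cavity_idx` marks the subset of atoms whose centroid defines the cavity
#' centre (the inward-pointing ring carbons in a macrocyclic host).
#'
#' @param atoms data.frame with columns `x`, `y`, `z` (A) and optionally
#'   `charge` (e), `r_min` (A), `epsilon` (kcal/mol), `element`.
#' @param cavity_idx integer indices into `atoms` of the cavity-defining
#'   atoms (non-empty).
#' @param cavity_axis unit vector of the cavity axis (default +z).
#' @return an object of class `host_geometry`.
#' @export
host_geometry <- function(atoms, cavity_idx = seq_len(nrow(atoms)),
                          cavity_axis = c(0, 0, 1)) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("x", "y", "z") %in% names(atoms)), nrow(atoms) >= 1)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$r_min)) atoms$r_min <- 3.8
  if (is.null(atoms$epsilon)) atoms$epsilon <- 0.1
  if (is.null(atoms$element)) atoms$element <- "C"
  stopifnot(all(is.finite(atoms$charge)))
  cavity_idx <- as.integer(cavity_idx)
  if (length(cavity_idx) == 0 || any(cavity_idx < 1) ||
      any(cavity_idx > nrow(atoms)))
    stop("cavity_idx must be a non-empty subset of atom rows", call. = FALSE)
  n <- sqrt(sum(cavity_axis^2))
  if (abs(n - 1) > 1e-8) cavity_axis <- cavity_axis / n
  structure(list(atoms = atoms, cavity_idx = cavity_idx,
                 cavity_axis = cavity_axis),
            class = "host_geometry")
}

#' @export
print.host_geometry <- function(x, ...) {
  cat("Host geometry:", nrow(x$atoms), "atoms,",
      length(x$cavity_idx), "cavity-defining;",
      "centre =", paste(round(cavity_center(x), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Generate an idealised macrocycle host geometry
#'
#' Places `n_ring` cavity atoms evenly on a circle of radius `ring_radius`
#' in the z = 0 plane (centroid at the origin by construction), emulating
#' the ring of inward-pointing CH carbons that defines the cavity centre of
#' a biotin[6]uril-type host.  Additional atoms (e.g. flanking polar sites
#' carrying charge for interaction-energy tests) can be appended via
#' `extra_atoms`.
#'
#' @param ring_radius circle radius in A (a macrocycle cavity is ~3 A).
#' @param n_ring number of ring atoms (>= 3; 12 for a biotin[6]uril-like
#'   ring).
#' @param ring_charge,ring_r_min,ring_epsilon parameters assigned to every
#'   ring atom.
#' @param extra_atoms optional data.frame of additional atoms (same columns
#'   as [host_geometry()] atoms); not part of the cavity definition.
#' @return a [host_geometry()].
#' @examples
#' h <- generate_host_geometry(ring_radius = 3, n_ring = 12)
#' cavity_center(h)  # (0,0,0)
#' @export
generate_host_geometry <- function(ring_radius = 3, n_ring = 12,
                                   ring_charge = 0, ring_r_min = 3.8,
                                   ring_epsilon = 0.1, extra_atoms = NULL) {
  stopifnot(ring_radius > 0, n_ring >= 3)
  theta <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  ring <- data.frame(x = ring_radius * cos(theta),
                     y = ring_radius * sin(theta),
                     z = 0,
                     charge = ring_charge, r_min = ring_r_min,
                     epsilon = ring_epsilon, element = "C")
  atoms <- ring
  if (!is.null(extra_atoms)) {
    extra_atoms <- as.data.frame(extra_atoms)
    for (col in c("charge", "r_min", "epsilon", "element")) {
      if (is.null(extra_atoms[[col]]))
        extra_atoms[[col]] <- ring[[col]][1]
    }
    atoms <- rbind(ring, extra_atoms[, names(ring)])
  }
  host_geometry(atoms, cavity_idx = seq_len(n_ring))
}

#' Cavity centre (centre of geometry of the cavity-defining atoms)
#'
#' The unweighted centroid of the cavity atoms.  For a ring of identical
#' carbons this coincides with the centre of mass.
#'
#' @param host a [host_geometry()].
#' @return numeric length-3 `(x, y, z)` in A.
#' @export
cavity_center <- function(host) {
  stopifnot(inherits(host, "host_geometry"))
  a <- host$atoms[host$cavity_idx, c("x", "y", "z")]
  if (nrow(a) == 0) stop("no cavity atoms", call. = FALSE)
  colMeans(as.matrix(a))
}

#' Reaction coordinate of an ion relative to the cavity centre
#'
#' The binding coordinate is the signed z separation between the ion and the
#' cavity centre; the lateral coordinate is the in-plane distance to the
#' cavity axis.  Translation-invariant: shifting ion and centre together
#' leaves both outputs unchanged.
#'
#' @param ion numeric length-3 ion position (A), or an n x 3 matrix.
#' @param center cavity centre, e.g. from [cavity_center()].
#' @return list with `z_dist` (signed, A) and `r_perp` (A); vectors when
#'   `ion` is a matrix.
#' @examples
#' reaction_coordinate(c(3, 4, 0), c(0, 0, 0))  # z_dist 0, r_perp 5
#' @export
reaction_coordinate <- function(ion, center) {
  if (is.null(dim(ion))) ion <- matrix(ion, ncol = 3)
  dx <- ion[, 1] - center[1]
  dy <- ion[, 2] - center[2]
  dz <- ion[, 3] - center[3]
  list(z_dist = unname(dz), r_perp = unname(sqrt(dx^2 + dy^2)))
}
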