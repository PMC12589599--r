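#' Build a planar toy molecule
#'
#' Generates a regular ring of `n_ring_atoms` atoms lying exactly in the
#' local x-z plane, centroid at the origin, with nearest-neighbour
#' distance `bond_length`.  It stands in for a rigid planar heterocycle
#' (elements alternate C/N, purine-like); the stacking analysis only
#' needs a rigid planar motif, not real molecular geometry.
#'
#' @param n_ring_atoms Number of ring atoms (>= 3).
#' @param bond_length Nearest-neighbour distance in angstrom (> 0).
#' @param seed Integer seed (kept for interface symmetry; the ring itself
#'   is deterministic).
#' @param label Text identifier.
#' @return An object of class `"molecule"`: a list with `label`, `atoms`
#'   (data frame of element and Cartesian x, y, z in the local frame) and
#'   `planarity_axis` (unit normal of the mean molecular plane).
#' @examples
#' m <- make_toy_molecule(6, 1.4)
#' nrow(m$atoms)
#' @export
make_toy_molecule <- function(n_ring_atoms, bond_length = 1.4, seed = 0,
                              label = sprintf("ring%d", n_ring_atoms)) {
  if (!is.finite(n_ring_atoms) || n_ring_atoms < 3)
    stop("invalid geometry: a planar ring needs at least 3 atoms")
  if (!is.finite(bond_length) || bond_length <= 0)
    stop("invalid geometry: bond_length must be positive")
  n <- as.integer(n_ring_atoms)
  r <- bond_length / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  atoms <- data.frame(
    element = rep_len(c("C", "N"), n),
    x = r * cos(ang),
    y = rep(0, n),
    z = r * sin(ang),
    stringsAsFactors = FALSE)
  structure(list(label = label, atoms = atoms,
                 planarity_axis = c(0, 1, 0),
                 bond_length = bond_length),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule '%s': %d atoms, planar (normal [%g %g %g])\n",
              x$label, nrow(x$atoms),
              x$planarity_axis[1], x$planarity_axis[2], x$planarity_axis[3]))
  invisible(x)
}

#' Maximum deviation of the atoms from the mean molecular plane
#' @param molecule A `"molecule"`.
#' @return Deviation in angstrom.
#' @export
molecule_planarity <- function(molecule) {
  p <- as.matrix(molecule$atoms[, c("x", "y", "z")])
  p <- sweep(p, 2, colMeans(p))
  max(abs(p %*% molecule$planarity_axis))
}

# radius of the smallest centred sphere containing all atoms
#' @noRd
molecule_radius <- function(molecule) {
  p <- as.matrix(molecule$atoms[, c("x", "y", "z")])
  max(sqrt(rowSums(p^2)))
}
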