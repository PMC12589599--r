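#' Build a 2D-periodic molecular layer motif
#'
#' Places `n_mol` copies of a planar molecule flat on an a x c footprint
#' (the hydrogen-bonded layer plane), one layer thick.  Centroids are
#' drawn at random (rejection sampling under a minimum-separation
#' constraint, periodic in the footprint lattice) and each molecule gets
#' a random in-plane rotation; placement is deterministic for a fixed
#' seed.
#'
#' @param molecule A `"molecule"` as from [make_toy_molecule()].
#' @param n_mol Number of molecules per footprint (>= 1).
#' @param footprint Numeric triple `c(a, c, angle)`: in-plane cell lengths
#'   in angstrom and the a-c inter-axial angle in degrees (default 90).
#' @param layer_spacing Repeat along the stacking normal, in angstrom.
#' @param seed Integer seed controlling placement.
#' @param min_sep Minimum centroid separation in angstrom.  Default
#'   2 * molecule radius + one bond length (non-overlapping rigid rings).
#' @param max_tries Rejection-sampling budget per molecule.
#' @return An object of class `"layer_motif"`.
#' @examples
#' motif <- make_layer_motif(make_toy_molecule(6), 2,
#'                           footprint = c(10, 14, 90), layer_spacing = 3.2,
#'                           seed = 1)
#' @export
make_layer_motif <- function(molecule, n_mol,
                             footprint = c(10.10, 17.91, 90),
                             layer_spacing = 12.54 / 4,
                             seed = 1,
                             min_sep = NULL,
                             max_tries = 5000L) {
  stopifnot(inherits(molecule, "molecule"))
  if (n_mol < 1) stop("n_mol must be >= 1")
  if (length(footprint) == 2) footprint <- c(footprint, 90)
  a <- footprint[1]; cc <- footprint[2]; ang <- footprint[3]
  if (a <= 0 || cc <= 0) stop("footprint lengths must be positive")
  if (layer_spacing <= 0) stop("layer_spacing must be positive")
  if (is.null(min_sep))
    min_sep <- 2 * molecule_radius(molecule) + molecule$bond_length
  m2 <- footprint_frame(a, cc, ang)

  placements <- with_seed(seed, {
    xs <- numeric(0); zs <- numeric(0); rot <- numeric(0)
    for (i in seq_len(n_mol)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- stats::runif(2)
        if (all(periodic_sep(cand[1], cand[2], xs, zs, m2) > min_sep)) {
          xs <- c(xs, cand[1]); zs <- c(zs, cand[2])
          rot <- c(rot, stats::runif(1, 0, 2 * pi))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("packing error: could not place molecule %d of %d without overlap (min_sep = %.2f A)",
                     i, n_mol, min_sep))
    }
    data.frame(x = xs, z = zs, angle = rot)
  })

  structure(list(molecule = molecule,
                 placements = placements,
                 footprint = list(a = a, c = cc, angle = ang),
                 layer_spacing = layer_spacing,
                 min_sep = min_sep,
                 seed = seed),
            class = "layer_motif")
}

#' @export
print.layer_motif <- function(x, ...) {
  cat(sprintf("layer motif: %d x '%s' on %.2f x %.2f A footprint (angle %.1f deg), layer spacing %.3f A\n",
              nrow(x$placements), x$molecule$label,
              x$footprint$a, x$footprint$c, x$footprint$angle,
              x$layer_spacing))
  invisible(x)
}

#' The default Form II-like layer motif
#'
#' Four planar six-membered rings on the published Form II footprint
#' (a = 10.10, c = 17.91 angstrom) with layer spacing b/4 = 12.54/4 =
#' 3.135 angstrom, i.e. Z' = 4 molecules per layer and four layers per
#' b repeat, giving Z = 16.
#'
#' @param seed Integer placement seed.
#' @return A `"layer_motif"`.
#' @export
form_ii_motif <- function(seed = 1) {
  make_layer_motif(make_toy_molecule(6, 1.4), n_mol = 4,
                   footprint = c(10.10, 17.91, 90),
                   layer_spacing = 12.54 / 4, seed = seed)
}

# 2x2 in-plane frame: columns are Cartesian images of the a and c axes
#' @noRd
footprint_frame <- function(a, c, angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(a, 0, c * cos(th), c * sin(th)), 2, 2)
}

# Cartesian distances from (x, z) to placed centroids, minimum image
#' @noRd
periodic_sep <- function(x, z, xs, zs, m2) {
  if (length(xs) == 0) return(Inf)
  dx <- x - xs; dz <- z - zs
  dx <- dx - round(dx); dz <- dz - round(dz)
  best <- rep(Inf, length(xs))
  for (sx in -1:1) for (sz in -1:1) {
    v <- m2 %*% rbind(dx + sx, dz + sz)
    best <- pmin(best, sqrt(colSums(v^2)))
  }
  best
}

#' Atom table of one layer
#'
#' Expands a motif to per-atom records: in-plane fractional coordinates
#' (of the footprint), the out-of-plane Cartesian offset (angstrom,
#' zero for planar molecules), element and molecule index.
#'
#' @param motif A `"layer_motif"`.
#' @return Data frame with columns `element`, `fx`, `fz`, `y`, `mol`.
#' @export
motif_atoms <- function(motif) {
  m2 <- footprint_frame(motif$footprint$a, motif$footprint$c,
                        motif$footprint$angle)
  m2inv <- solve(m2)
  out <- vector("list", nrow(motif$placements))
  at <- motif$molecule$atoms
  for (i in seq_len(nrow(motif$placements))) {
    p <- motif$placements[i, ]
    rot <- matrix(c(cos(p$angle), sin(p$angle),
                    -sin(p$angle), cos(p$angle)), 2, 2)
    xz <- rot %*% rbind(at$x, at$z)          # rotate in the layer plane
    cart <- as.numeric(m2 %*% c(p$x, p$z))   # centroid, Cartesian
    fr <- m2inv %*% (xz + cart)              # back to fractional, unwrapped
    out[[i]] <- data.frame(element = at$element,
                           fx = fr[1, ], fz = fr[2, ],
                           y = at$y, mol = i,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Minimum inter-centroid distance of a motif (periodic, Cartesian)
#' @param motif A `"layer_motif"`.
#' @return Distance in angstrom (`Inf` for a single molecule).
#' @export
motif_min_separation <- function(motif) {
  p <- motif$placements
  if (nrow(p) < 2) return(Inf)
  m2 <- footprint_frame(motif$footprint$a, motif$footprint$c,
                        motif$footprint$angle)
  best <- Inf
  for (i in 2:nrow(p))
    best <- min(best, min(periodic_sep(p$x[i], p$z[i],
                                       p$x[seq_len(i - 1)],
                                       p$z[seq_len(i - 1)], m2)))
  best
}
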