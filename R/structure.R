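#' Atomic crystal structure in P1
#'
#' Container used throughout: a cell plus a per-atom table of fractional
#' coordinates wrapped to [0, 1), with optional molecule id and layer
#' index.  `ref_cell` is the cell in whose fractional units interlayer
#' vectors are reported (for stacked supercells this is the single-cell
#' repeat, e.g. the Form II cell; it defaults to the structure's own
#' cell).
#'
#' @param cell A `"cell"`.
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `mol` and `layer`.
#' @param ref_cell Reference `"cell"` for fractional reporting.
#' @param meta Optional named list (seed, sequence string, ...).
#' @return An object of class `"crystal_structure"`.
#' @export
crystal_structure <- function(cell, atoms, ref_cell = cell, meta = list()) {
  stopifnot(inherits(cell, "cell"), is.data.frame(atoms))
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns element, x, y, z")
  if (nrow(atoms) == 0) stop("empty structure")
  if (!"mol" %in% names(atoms)) atoms$mol <- NA_integer_
  if (!"layer" %in% names(atoms)) atoms$layer <- NA_integer_
  atoms[, c("x", "y", "z")] <- lapply(atoms[, c("x", "y", "z")], wrap_frac)
  structure(list(cell = cell, atoms = atoms, ref_cell = ref_cell,
                 meta = meta),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  nl <- n_layers(x)
  cat(sprintf("crystal structure: %d atoms%s\n", nrow(x$atoms),
              if (is.na(nl)) "" else sprintf(" in %d layers", nl)))
  print(x$cell)
  invisible(x)
}

#' Number of layers carried by a structure
#' @param structure A `"crystal_structure"`.
#' @return Integer layer count, or `NA` if no layer indices are stored.
#' @export
n_layers <- function(structure) {
  l <- structure$atoms$layer
  if (all(is.na(l))) NA_integer_ else length(unique(l[!is.na(l)]))
}

# wrap to the half-open interval [0, 1); snap exact 1s from roundoff
#' @noRd
wrap_frac <- function(x) {
  y <- x - floor(x)
  y[y >= 1 - 1e-12] <- 0
  y
}

#' Molecule centroids of a structure
#'
#' Centroids are computed per molecule id with per-molecule unwrapping
#' (atoms are shifted by whole lattice vectors to sit near the first
#' atom before averaging), so molecules straddling a cell edge are
#' handled correctly.  The centroid itself is wrapped back to [0, 1).
#'
#' @param structure A `"crystal_structure"` with molecule ids.
#' @return Data frame `mol`, `layer`, `x`, `y`, `z` (fractional).
#' @export
molecule_centroids <- function(structure) {
  at <- structure$atoms
  if (all(is.na(at$mol))) stop("structure carries no molecule ids")
  sp <- split(at, at$mol)
  res <- lapply(sp, function(d) {
    p <- as.matrix(d[, c("x", "y", "z")])
    anchor <- p[1, ]
    p <- sweep(p, 2, anchor)
    p <- p - round(p)                      # unwrap relative to first atom
    ctr <- anchor + colMeans(p)
    data.frame(mol = d$mol[1], layer = d$layer[1],
               x = ctr[1], y = ctr[2], z = ctr[3])
  })
  out <- do.call(rbind, res)
  out[, c("x", "y", "z")] <- lapply(out[, c("x", "y", "z")], wrap_frac)
  rownames(out) <- NULL
  out
}
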