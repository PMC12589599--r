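#' Crystallographic unit cell
#'
#' Constructs a unit cell from lengths (angstrom) and inter-axial angles
#' (degrees).  The default angles give an orthorhombic/cubic cell.
#'
#' @param a,b,c Cell edge lengths in angstrom (> 0).
#' @param alpha,beta,gamma Inter-axial angles in degrees, each in (0, 180).
#'   `alpha` is the angle between **b** and **c**, `beta` between **a** and
#'   **c**, `gamma` between **a** and **b**.
#' @return An object of class `"cell"`.
#' @examples
#' form_ii_cell()
#' cell(10, 10, 10)
#' @export
cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  lens <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("cell lengths must be finite and positive")
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180))
    stop("cell angles must lie in the open interval (0, 180) degrees")
  x <- structure(list(a = a, b = b, c = c,
                      alpha = alpha, beta = beta, gamma = gamma),
                 class = "cell")
  v <- cell_volume(x)
  if (!is.finite(v) || v <= 1e-9) stop("degenerate cell: non-positive volume")
  x
}

#' @export
print.cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f A, alpha=%.3f beta=%.3f gamma=%.3f deg, V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' The Form II xanthine-like reference cell
#'
#' Orthorhombic cell with the published Form II lattice parameters
#' (a = 10.10, b = 12.54, c = 17.91 angstrom; all angles 90 degrees).
#' The b axis is the stacking direction and contains four layers.
#'
#' @return A `"cell"` object.
#' @export
form_ii_cell <- function() cell(10.10, 12.54, 17.91)

#' Unit-cell volume
#'
#' @param x A `"cell"` object.
#' @return Volume in cubic angstrom.
#' @export
cell_volume <- function(x) {
  ca <- cos(x$alpha * pi / 180); cb <- cos(x$beta * pi / 180)
  cg <- cos(x$gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(0)
  x$a * x$b * x$c * sqrt(arg)
}

#' Orthonormalization frame of a cell
#'
#' Returns the 3x3 matrix whose columns are the Cartesian images of the
#' cell vectors **a**, **b**, **c**, in the standard crystallographic
#' convention: **a** along x, **b** in the x-y plane.  Fractional
#' coordinates map to Cartesian angstrom via `A %*% x_frac`.
#'
#' @param cell A `"cell"` object.
#' @return A 3x3 numeric matrix.
#' @export
orthonormal_frame <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  if (abs(sg) < 1e-12) stop("singular frame: gamma is degenerate")
  cy <- (ca - cb * cg) / sg
  cz2 <- 1 - cb^2 - cy^2
  if (cz2 <= 0) stop("singular frame: cell angles are degenerate")
  m <- matrix(c(cell$a, 0, 0,
                cell$b * cg, cell$b * sg, 0,
                cell$c * cb, cell$c * cy, cell$c * sqrt(cz2)),
              nrow = 3, ncol = 3)
  colnames(m) <- c("a", "b", "c")
  m
}

#' Direct-space metric tensor G = t(A) %*% A
#' @noRd
metric_tensor <- function(cell) {
  a <- orthonormal_frame(cell)
  crossprod(a)
}

#' d-spacing of a reflection
#'
#' Computes interplanar spacings from the reciprocal metric tensor:
#' 1/d^2 = h^T G* h.
#'
#' @param cell A `"cell"` object.
#' @param hkl Integer triple, or an n x 3 matrix of triples.
#' @return d-spacing(s) in angstrom.
#' @examples
#' d_spacing(form_ii_cell(), c(0, 1, 0))  # = b = 12.54
#' @export
d_spacing <- function(cell, hkl) {
  h <- rbind_hkl(hkl)
  if (any(rowSums(h != 0) == 0)) stop("d-spacing undefined for (0,0,0)")
  gstar <- solve(metric_tensor(cell))
  inv_d2 <- rowSums((h %*% gstar) * h)
  1 / sqrt(inv_d2)
}

# coerce a triple or matrix of triples to an n x 3 matrix
#' @noRd
rbind_hkl <- function(hkl) {
  if (is.matrix(hkl)) {
    stopifnot(ncol(hkl) == 3)
    hkl
  } else {
    stopifnot(length(hkl) == 3)
    matrix(hkl, nrow = 1)
  }
}
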