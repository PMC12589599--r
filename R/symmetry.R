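#' Symmetry operator sets for the space groups used here
#'
#' Hard-coded fractional-convention operators for P1, P2_1/c and
#' P2_1 2_1 2_1 (standard settings, International Tables choices).
#' Each operator is a list with an integer 3x3 `R` and a translation
#' `t` with components in [0, 1).
#'
#' @param group One of `"P1"`, `"P21/c"`, `"P212121"`.
#' @return List of operators; the first is always the identity.
#' @export
symmetry_ops <- function(group = c("P1", "P21/c", "P212121")) {
  group <- match.arg(group)
  op <- function(r, t) list(R = matrix(as.numeric(r), 3, 3, byrow = TRUE),
                            t = as.numeric(t))
  id <- op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0))
  switch(group,
    "P1" = list(id),
    "P21/c" = list(
      id,
      op(c(-1, 0, 0, 0, -1, 0, 0, 0, -1), c(0, 0, 0)),          # -x,-y,-z
      op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 0.5, 0.5)),       # -x,1/2+y,1/2-z
      op(c(1, 0, 0, 0, -1, 0, 0, 0, 1), c(0, 0.5, 0.5))),       # x,1/2-y,1/2+z
    "P212121" = list(
      id,
      op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0.5, 0, 0.5)),       # 1/2-x,-y,1/2+z
      op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(0.5, 0.5, 0)),       # 1/2+x,1/2-y,-z
      op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 0.5, 0.5))))      # -x,1/2+y,1/2-z
}

#' Expand an asymmetric unit by symmetry operators
#'
#' Applies every operator to every atom and wraps the images into
#' [0, 1).  No special-position merging is attempted: if two images of
#' the expanded set fall within 0.1 angstrom of each other (minimum
#' image, Cartesian), a special-position error is raised.
#'
#' @param asym_atoms n x 3 matrix (or data frame with x, y, z) of
#'   fractional coordinates of the asymmetric unit.
#' @param ops Operator list as from [symmetry_ops()]; the first must be
#'   the identity.
#' @param cell The `"cell"` of the structure.
#' @param elements Optional character vector of element symbols,
#'   recycled over the asymmetric atoms (default `"C"`).
#' @return A `"crystal_structure"` with `length(ops) * n` atoms.
#' @examples
#' expand_symmetry(matrix(c(0.1, 0.2, 0.3), 1), symmetry_ops("P212121"),
#'                 cell(10, 12, 14))
#' @export
expand_symmetry <- function(asym_atoms, ops, cell, elements = "C") {
  if (is.data.frame(asym_atoms))
    asym_atoms <- as.matrix(asym_atoms[, c("x", "y", "z")])
  if (!is.matrix(asym_atoms)) asym_atoms <- matrix(asym_atoms, ncol = 3)
  if (length(ops) == 0) stop("ops must be non-empty")
  first <- ops[[1]]
  if (!isTRUE(all.equal(first$R, diag(3))) || any(first$t != 0))
    stop("the first operator must be the identity")
  n <- nrow(asym_atoms)
  elements <- rep_len(elements, n)
  pos <- do.call(rbind, lapply(ops, function(o) {
    t(o$R %*% t(asym_atoms) + o$t)
  }))
  pos <- apply(pos, 2, wrap_frac)
  if (!is.matrix(pos)) pos <- matrix(pos, ncol = 3)
  # collision check, minimum image in Cartesian
  frame <- orthonormal_frame(cell)
  if (nrow(pos) > 1) {
    for (i in 1:(nrow(pos) - 1)) {
      d <- sweep(pos[(i + 1):nrow(pos), , drop = FALSE], 2, pos[i, ])
      d <- d - round(d)
      dist <- sqrt(colSums((frame %*% t(d))^2))
      if (any(dist < 0.1))
        stop("special-position error: symmetry images collide within 0.1 A")
    }
  }
  crystal_structure(cell,
                    data.frame(element = rep(elements, length(ops)),
                               x = pos[, 1], y = pos[, 2], z = pos[, 3],
                               stringsAsFactors = FALSE))
}
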