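#' Orientation matrix (UB)
#'
#' The matrix mapping fractional crystal coordinates to the Cartesian
#' laboratory frame, `lab = UB %*% x_frac`.  Constructed either from an
#' explicit 3x3 matrix (validated against the cell metric) or from a
#' cell plus a laboratory rotation.
#'
#' @param cell A `"cell"`.
#' @param ub Optional explicit 3x3 matrix; default
#'   `rotation %*% orthonormal_frame(cell)`.
#' @param rotation Optional 3x3 laboratory rotation applied to the
#'   standard orthonormalization frame.
#' @param tol Relative tolerance for the metric consistency check
#'   (default 1e-6); set `Inf` to skip.
#' @return An object of class `"orientation_matrix"`.
#' @export
orientation_matrix <- function(cell, ub = NULL, rotation = diag(3),
                               tol = 1e-6) {
  stopifnot(inherits(cell, "cell"))
  if (is.null(ub)) ub <- rotation %*% orthonormal_frame(cell)
  ub <- unname(as.matrix(ub))
  stopifnot(all(dim(ub) == c(3, 3)))
  if (abs(det(ub)) < 1e-12) stop("orientation matrix is singular")
  g <- metric_tensor(cell)
  rel <- norm(crossprod(ub) - g, "F") / norm(g, "F")
  if (rel > tol)
    stop(sprintf("orientation matrix inconsistent with the cell metric (relative residual %.3g)", rel))
  structure(list(ub = ub, cell = cell), class = "orientation_matrix")
}

#' Relate two crystal orientations
#'
#' Computes the operator T = UB_parent^-1 UB_twin expressed in
#' fractional crystal coordinates (it maps twin-domain fractional
#' coordinates onto the parent lattice) and characterizes it as a
#' potential twin law via [characterize_operator()].  The
#' metric-preservation residual ||T' G T - G|| / ||G|| is reported; a
#' residual above `metric_tol` flags the pair as two merely misoriented
#' crystals rather than a twin (warning on the returned object, not an
#' error).
#'
#' @param parent,twin `"orientation_matrix"` objects sharing the same
#'   cell (same polymorph).
#' @param metric_tol Relative metric-preservation tolerance
#'   (default 1e-4).
#' @param ... Passed to [characterize_operator()].
#' @return A `"twin_operator"`.
#' @export
relate_orientations <- function(parent, twin, metric_tol = 1e-4, ...) {
  stopifnot(inherits(parent, "orientation_matrix"),
            inherits(twin, "orientation_matrix"))
  same <- isTRUE(all.equal(unlist(parent$cell), unlist(twin$cell),
                           tolerance = 1e-8))
  if (!same) stop("parent and twin must share the same cell")
  tmat <- solve(parent$ub) %*% twin$ub
  op <- characterize_operator(tmat, parent$cell, ...)
  g <- metric_tensor(parent$cell)
  res <- norm(t(tmat) %*% g %*% tmat - g, "F") / norm(g, "F")
  op$metric_residual <- res
  op$is_lattice_operation <- res <= metric_tol
  if (!op$is_lattice_operation)
    warning(sprintf("operator does not preserve the lattice metric (residual %.3g): possibly two misoriented crystals, not a twin", res))
  op
}

#' Characterize a lattice operator as a twin law
#'
#' Given an operator `T` in fractional coordinates, forms its Cartesian
#' image R = A T A^-1 (A the cell orthonormalization) and reports:
#' determinant sign; for proper operators the rotation angle (from the
#' trace) and axis (+1 eigenvector) expressed as a real-valued
#' direct-lattice triple plus the best small-integer approximation with
#' its angular error; for improper operators, both the mirror/rotoinversion
#' description (with Miller indices of the mirror plane when the operator
#' is a true reflection, i.e. its proper equivalent is a two-fold) and
#' the equivalent proper rotation obtained by composing with inversion —
#' the two descriptions a centrosymmetric structure cannot distinguish.
#'
#' Axes transform contravariantly (direct-lattice triples, via A) and
#' plane normals covariantly (reciprocal-lattice triples, via
#' (A^-1)^T); mixing the two is the classic indexing bug this keeps out.
#'
#' @param tmat 3x3 operator in fractional coordinates.
#' @param cell The `"cell"`.
#' @param max_index Brute-force bound for integer axis search
#'   (default 12).
#' @param tol Angular tolerance in degrees for calling an axis "integer"
#'   (default 0.5); larger misfits are still reported with their best
#'   integer fit and residual.
#' @param iso_tol Frobenius tolerance on orthogonality of the Cartesian
#'   image (default 1e-6).
#' @return A `"twin_operator"` list: `matrix`, `det`, `proper`, `angle`
#'   (degrees, in [0, 180]), `axis` (real direct-lattice triple, largest
#'   component normalized to 1), `axis_integer`, `axis_angular_error`
#'   (degrees), `mirror` (Miller triple or NULL), `equivalents`.
#' @export
characterize_operator <- function(tmat, cell, max_index = 12, tol = 0.5,
                                  iso_tol = 1e-6) {
  tmat <- unname(as.matrix(tmat))
  stopifnot(all(dim(tmat) == c(3, 3)))
  if (abs(det(tmat)) < 1e-12) stop("operator is singular")
  a <- orthonormal_frame(cell)
  rc <- a %*% tmat %*% solve(a)
  if (norm(crossprod(rc) - diag(3), "F") > iso_tol)
    stop("not an isometry: Cartesian image of the operator is not orthogonal")
  dt <- det(rc)
  proper <- dt > 0
  rp <- if (proper) rc else -rc            # proper equivalent
  ang <- rotation_angle(rp)

  axis_cart <- if (ang < 1e-9) NULL else rotation_axis(rp)
  axis_frac <- NULL; axis_int <- NULL; axis_err <- NA_real_
  if (!is.null(axis_cart)) {
    v <- solve(a, axis_cart)               # direct-lattice (contravariant)
    v <- v / max(abs(v))
    axis_frac <- as.numeric(v)
    fit <- rationalize_direction(axis_cart, a, max_index)
    axis_int <- fit$triple
    axis_err <- fit$angle
  }

  mirror <- NULL
  if (!proper && abs(ang - 180) < 1e-6) {
    # reflection: mirror normal = two-fold axis of the proper equivalent
    b <- t(solve(a))                       # reciprocal frame
    hfit <- rationalize_direction(axis_cart, b, max_index)
    hreal <- as.numeric(t(a) %*% axis_cart)
    hreal <- hreal / max(abs(hreal))
    mirror <- list(hkl = hfit$triple, hkl_real = hreal,
                   angular_error = hfit$angle)
  }

  equivalents <- if (proper) {
    list(sprintf("proper rotation of %.4f deg", ang))
  } else if (abs(ang - 180) < 1e-6) {
    list("reflection (mirror) description",
         "180 deg rotation about the mirror normal, composed with inversion",
         "indistinguishable for a centrosymmetric structure")
  } else {
    list(sprintf("rotoinversion: %.4f deg rotation composed with inversion", ang))
  }

  structure(list(matrix = tmat, det = dt, proper = proper,
                 angle = ang,
                 axis = axis_frac,
                 axis_cart = if (is.null(axis_cart)) NULL else as.numeric(axis_cart),
                 axis_integer = axis_int,
                 axis_angular_error = axis_err,
                 axis_is_rational = is.finite(axis_err) && axis_err <= tol,
                 mirror = mirror,
                 equivalents = equivalents,
                 cell = cell),
            class = "twin_operator")
}

#' @export
print.twin_operator <- function(x, ...) {
  kind <- if (x$proper) "proper rotation" else
    if (!is.null(x$mirror)) "reflection (improper)" else "rotoinversion (improper)"
  cat(sprintf("twin operator: %s, det = %+.3f, angle = %.4f deg\n",
              kind, x$det, x$angle))
  if (!is.null(x$axis))
    cat(sprintf("  axis [%s] ~ [%s] (integer fit, %.3f deg off)\n",
                paste(sprintf("%.3f", x$axis), collapse = " "),
                paste(x$axis_integer, collapse = " "),
                x$axis_angular_error))
  if (!is.null(x$mirror))
    cat(sprintf("  mirror plane ~ (%s), %.3f deg off\n",
                paste(x$mirror$hkl, collapse = " "), x$mirror$angular_error))
  if (!is.null(x$metric_residual))
    cat(sprintf("  metric residual %.3g (%s)\n", x$metric_residual,
                if (isTRUE(x$is_lattice_operation)) "lattice operation"
                else "NOT a lattice operation"))
  invisible(x)
}

#' @noRd
rotation_angle <- function(r) {
  tr <- sum(diag(r))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# unit rotation axis of a proper rotation (angle > 0)
#' @noRd
rotation_axis <- function(r) {
  ev <- eigen(r)
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v <- v / sqrt(sum(v^2))
  # deterministic sign: largest-magnitude component positive
  j <- which.max(abs(v))
  if (v[j] < 0) v <- -v
  v
}

.triple_cache <- new.env(parent = emptyenv())

# primitive integer triples with |component| <= max_index, cached
#' @noRd
primitive_triples <- function(max_index) {
  key <- as.character(max_index)
  if (!is.null(.triple_cache[[key]])) return(.triple_cache[[key]])
  idx <- seq(-max_index, max_index)
  g <- as.matrix(expand.grid(u = idx, v = idx, w = idx))
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  gcd_s <- function(x, y) { while (y) { t <- y; y <- x %% y; x <- t }; x }
  d <- mapply(function(u, v, w) gcd_s(gcd_s(u, v), w),
              abs(g[, 1]), abs(g[, 2]), abs(g[, 3]))
  g <- unique(g / d)
  .triple_cache[[key]] <- g
  g
}

# best integer triple whose image under `frame` is most parallel to dir
#' @noRd
rationalize_direction <- function(dir_cart, frame, max_index = 12) {
  dir_cart <- dir_cart / sqrt(sum(dir_cart^2))
  g <- primitive_triples(max_index)
  v <- frame %*% t(g)
  cosang <- abs(as.numeric(dir_cart %*% v) / sqrt(colSums(v^2)))
  i <- which.max(cosang)
  triple <- as.integer(g[i, ])
  # canonical sign: first nonzero component positive
  nz <- which(triple != 0)[1]
  if (triple[nz] < 0) triple <- -triple
  list(triple = triple,
       angle = acos(pmin(1, cosang[i])) * 180 / pi)
}

#' Is a lattice plane invariant under a twin operator?
#'
#' Maps the plane normal through the operator (reciprocal-space,
#' covariant action) and reports whether the image is parallel or
#' anti-parallel to the original within `tol` degrees, plus the
#' deviation angle.
#'
#' @param op A `"twin_operator"` (or a plain fractional 3x3 matrix).
#' @param plane Miller triple, not all zero.
#' @param cell The `"cell"` (taken from the operator if omitted).
#' @param tol Parallelism tolerance in degrees (default 0.5).
#' @return List `invariant` (logical), `deviation` (degrees, distance to
#'   the nearer of parallel/anti-parallel), `antiparallel` (logical).
#' @export
plane_invariance_check <- function(op, plane, cell = NULL, tol = 0.5) {
  if (inherits(op, "twin_operator")) {
    if (is.null(cell)) cell <- op$cell
    tmat <- op$matrix
  } else tmat <- unname(as.matrix(op))
  if (all(plane == 0)) stop("plane indices must not all be zero")
  stopifnot(inherits(cell, "cell"))
  a <- orthonormal_frame(cell)
  b <- t(solve(a))
  n0 <- as.numeric(b %*% plane)
  rc <- a %*% tmat %*% solve(a)
  n1 <- as.numeric(rc %*% n0)
  cosang <- sum(n0 * n1) / sqrt(sum(n0^2) * sum(n1^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  dev <- min(ang, 180 - ang)
  list(invariant = dev <= tol, deviation = dev,
       antiparallel = ang > 90)
}

#' Cartesian reflection across a plane of a cell
#'
#' Convenience builder for twin constructions: the orthogonal matrix
#' I - 2 n n^T, with n the unit normal of the given Miller plane.
#'
#' @param cell A `"cell"`.
#' @param plane Miller triple.
#' @return 3x3 orthogonal matrix with determinant -1.
#' @export
reflection_about_plane <- function(cell, plane) {
  if (all(plane == 0)) stop("plane indices must not all be zero")
  b <- t(solve(orthonormal_frame(cell)))
  n <- as.numeric(b %*% plane)
  n <- n / sqrt(sum(n^2))
  diag(3) - 2 * outer(n, n)
}

#' Cartesian rotation about an axis
#'
#' Rodrigues rotation matrix for an angle (degrees) about a Cartesian
#' axis direction.
#'
#' @param axis Cartesian 3-vector (need not be normalized).
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  n <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}
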