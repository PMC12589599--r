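#' The four-vector interlayer stacking family
#'
#' Interlayer translations in the layered polytypes studied here take
#' one of four values sharing a magnitude: in fractional coordinates of
#' the reference (Form II-like) cell,
#' \deqn{A = (+u, v, +w),\; B = (-u, v, +w),\; C = (-u, v, -w),\; D = (+u, v, -w),}
#' so the in-plane parts obey C = -A and D = -B, A and B are related by
#' the mirror that flips the a-component, and the in-plane parts sum to
#' zero over the family.  Defaults are the published components
#' u = 0.377 (a), v = 0.250 (b, the stacking advance), w = 0.041 (c).
#'
#' The explicit sign assignment is a convention of this package: the
#' source analysis fixes only the mirror relations and C = -A, D = -B.
#'
#' @param u,w Non-negative in-plane fractional components (a and c).
#' @param v Fractional advance along the stacking axis, 0 < v <= 1.
#' @return An object of class `"stacking_family"`: a 4 x 3 matrix of
#'   vectors with rows A, B, C, D plus the components as attributes.
#' @examples
#' fam <- make_vector_family()
#' fam$vectors["C", ]   # (-0.377, 0.250, -0.041)
#' @export
make_vector_family <- function(u = 0.377, v = 0.250, w = 0.041) {
  if (!is.finite(v) || v <= 0)
    stop("no stacking advance: v must be positive")
  if (v > 1) stop("v must be <= 1 (fraction of the reference repeat)")
  if (u < 0 || w < 0) stop("u and w must be non-negative")
  vec <- rbind(A = c(u, v, w),
               B = c(-u, v, w),
               C = c(-u, v, -w),
               D = c(u, v, -w))
  colnames(vec) <- c("u", "v", "w")
  structure(list(vectors = vec, u = u, v = v, w = w),
            class = "stacking_family")
}

#' @export
print.stacking_family <- function(x, ...) {
  cat(sprintf("stacking vector family (u=%g, v=%g, w=%g):\n", x$u, x$v, x$w))
  print(x$vectors)
  invisible(x)
}

.stack_labels <- c("A", "B", "C", "D")

#' @noRd
check_labels <- function(labels) {
  labels <- as.character(unlist(strsplit(paste(labels, collapse = ""), "")))
  bad <- setdiff(labels, .stack_labels)
  if (length(bad))
    stop("unknown stacking label(s): ", paste(unique(bad), collapse = ", "))
  labels
}

#' Ordered (periodic) stacking sequence
#'
#' Cyclic repetition of a pattern truncated to `n_layers` labels, e.g.
#' "AB" for the Form I polytype and "ABCD" for Form II.
#'
#' @param pattern Character vector of labels or a single string such as
#'   `"ABCD"`.
#' @param n_layers Number of layers (>= 1).
#' @return A `"stack_sequence"` with provenance `"ordered"`.
#' @examples
#' periodic_sequence("AB", 5)   # A B A B A
#' @export
periodic_sequence <- function(pattern, n_layers) {
  pattern <- check_labels(pattern)
  if (length(pattern) == 0) stop("pattern must be non-empty")
  if (n_layers < 1) stop("n_layers must be >= 1")
  structure(list(labels = rep_len(pattern, n_layers),
                 provenance = "ordered",
                 base_pattern = pattern,
                 p_fault = 0,
                 fault_positions = integer(0),
                 seed = NA_integer_),
            class = "stack_sequence")
}

#' Randomly faulted stacking sequence
#'
#' Starts from the ordered sequence and, independently at each interface
#' (0-based positions 0 .. n-2; the final label of the sequence is never
#' consumed by the builder and is left unfaulted), replaces the expected
#' label with probability `p_fault` by a uniformly chosen *different*
#' label from \{A, B, C, D\}.  This is the supercell fault protocol used
#' for the 20-layer (five-cell) disorder models.
#'
#' @param base_pattern Ordered pattern, e.g. `"ABCD"`.
#' @param n_layers Number of layers.
#' @param p_fault Fault probability per interface, in [0, 1].
#' @param seed Integer seed; the draw is deterministic per seed.
#' @return A `"stack_sequence"` with provenance `"faulted"` and the
#'   0-based fault positions recorded.
#' @export
faulted_sequence <- function(base_pattern, n_layers, p_fault = 0.1,
                             seed = 1) {
  if (!is.finite(p_fault) || p_fault < 0 || p_fault > 1)
    stop("p_fault must be a probability in [0, 1]")
  seq0 <- periodic_sequence(base_pattern, n_layers)
  labels <- seq0$labels
  n_if <- max(n_layers - 1L, 0L)          # usable interfaces
  faults <- integer(0)
  if (n_if > 0 && p_fault > 0) {
    labels <- with_seed(seed, {
      hit <- stats::runif(n_if) < p_fault
      for (i in which(hit)) {
        alt <- setdiff(.stack_labels, labels[i])
        labels[i] <- alt[sample.int(3L, 1L)]
      }
      faults <- which(hit) - 1L          # assigned in this function's frame
      labels
    })
  }
  structure(list(labels = labels,
                 provenance = "faulted",
                 base_pattern = seq0$base_pattern,
                 p_fault = p_fault,
                 fault_positions = faults,
                 seed = as.integer(seed)),
            class = "stack_sequence")
}

#' @export
print.stack_sequence <- function(x, ...) {
  s <- paste(x$labels, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("stack sequence (%s, %d layers): %s\n",
              x$provenance, length(x$labels), s))
  if (x$provenance == "faulted")
    cat(sprintf("  p_fault = %g, %d fault(s), seed %d\n",
                x$p_fault, length(x$fault_positions), x$seed))
  invisible(x)
}

#' @export
format.stack_sequence <- function(x, ...) paste(x$labels, collapse = "")

#' Build a stacked supercell structure
#'
#' Layer k (0-based) is the motif translated by the cumulative sum of
#' the first k sequence vectors; in-plane components are wrapped modulo
#' the footprint lattice.  The supercell stacking axis (b) has length
#' `n_layers * layer_spacing`; the reference cell stored on the result
#' has `b_ref = layer_spacing / v`, so recovered interlayer vectors come
#' out in single-cell (Form II-like) fractional units.
#'
#' @param motif A `"layer_motif"`.
#' @param sequence A `"stack_sequence"` (or label string / vector).
#' @param family A `"stacking_family"`.
#' @return A `"crystal_structure"` with per-atom layer indices 0..n-1
#'   and molecule ids.
#' @examples
#' st <- build_stack(form_ii_motif(), periodic_sequence("ABCD", 8),
#'                   make_vector_family())
#' n_layers(st)
#' @export
build_stack <- function(motif, sequence, family = make_vector_family()) {
  stopifnot(inherits(motif, "layer_motif"),
            inherits(family, "stacking_family"))
  if (!inherits(sequence, "stack_sequence"))
    sequence <- periodic_sequence(sequence, length(check_labels(sequence)))
  labels <- sequence$labels
  n <- length(labels)
  if (n < 1) stop("sequence must contain at least one layer")

  vecs <- family$vectors[labels, , drop = FALSE]
  # cumulative displacement reaching layer k uses the first k vectors
  cum_u <- c(0, cumsum(vecs[, "u"]))[seq_len(n)]
  cum_w <- c(0, cumsum(vecs[, "w"]))[seq_len(n)]

  b_super <- n * motif$layer_spacing
  b_ref <- motif$layer_spacing / family$v
  at <- motif_atoms(motif)
  n_at <- nrow(at)
  n_mol_layer <- max(at$mol)

  k <- rep(0:(n - 1), each = n_at)
  atoms <- data.frame(
    element = rep(at$element, n),
    x = rep(at$fx, n) + cum_u[k + 1],
    y = (k * motif$layer_spacing + rep(at$y, n)) / b_super,
    z = rep(at$fz, n) + cum_w[k + 1],
    mol = rep(at$mol, n) + k * n_mol_layer,
    layer = k,
    stringsAsFactors = FALSE)

  sc <- cell(motif$footprint$a, b_super, motif$footprint$c,
             alpha = 90, beta = motif$footprint$angle, gamma = 90)
  rc <- cell(motif$footprint$a, b_ref, motif$footprint$c,
             alpha = 90, beta = motif$footprint$angle, gamma = 90)
  crystal_structure(sc, atoms, ref_cell = rc,
                    meta = list(sequence = paste(labels, collapse = ""),
                                provenance = sequence$provenance,
                                p_fault = sequence$p_fault,
                                seed = sequence$seed,
                                layer_spacing = motif$layer_spacing,
                                family = family))
}

#' Smallest repeat period of a stacking sequence
#'
#' Returns the smallest n >= 1 such that the cumulative translation over
#' the first n vectors is a whole lattice vector of the reference cell:
#' in-plane components congruent to 0 (mod 1) and the stacking component
#' an integer, each within `tol`.  `NA` if no n up to the sequence
#' length qualifies — e.g. the AB (Form I-like) sequence expressed in
#' this frame, whose layer positions never repeat.
#'
#' @param sequence_labels Label vector or string (e.g. the first 100
#'   labels of a cyclic pattern).
#' @param family A `"stacking_family"`.
#' @param tol Tolerance on the fractional closure (default 1e-9).
#' @return Integer period, or `NA_integer_`.
#' @examples
#' detect_period(periodic_sequence("ABCD", 12)$labels, make_vector_family())
#' @export
detect_period <- function(sequence_labels, family, tol = 1e-9) {
  if (inherits(sequence_labels, "stack_sequence"))
    sequence_labels <- sequence_labels$labels
  labels <- check_labels(sequence_labels)
  if (tol <= 0) stop("tol must be positive")
  vecs <- family$vectors[labels, , drop = FALSE]
  cu <- cumsum(vecs[, "u"]); cv <- cumsum(vecs[, "v"])
  cw <- cumsum(vecs[, "w"])
  frac_dist <- function(x) abs(x - round(x))
  ok <- frac_dist(cu) <= tol & frac_dist(cw) <= tol & frac_dist(cv) <= tol
  if (!any(ok)) return(NA_integer_)
  as.integer(which(ok)[1])
}

# reduce an in-plane fractional displacement to the minimum-magnitude
# representative modulo the footprint lattice (Cartesian metric m2);
# ties within 1e-9 broken towards non-negative a, then non-negative c
#' @noRd
reduce_inplane <- function(du, dw, m2) {
  du <- du - round(du); dw <- dw - round(dw)
  cand <- expand.grid(sx = -1:1, sz = -1:1)
  u <- du + cand$sx; w <- dw + cand$sz
  mag <- sqrt(colSums((m2 %*% rbind(u, w))^2))
  best <- min(mag)
  tied <- which(mag <= best + 1e-9)
  if (length(tied) > 1) {
    pref <- order(u[tied] < -1e-12, w[tied] < -1e-12,
                  mag[tied])              # non-negative a, then c, then mag
    tied <- tied[pref]
  }
  i <- tied[1]
  c(u[i], w[i])
}

#' Recover interlayer translation vectors from a structure
#'
#' Assumes rigid-body stacking: every layer is the same motif translated
#' as a whole.  For each adjacent layer pair the molecule centroids of
#' layer k+1 are matched to layer k and the common displacement is
#' returned, with the in-plane part reduced modulo the footprint lattice
#' to the representative of minimum Cartesian magnitude (the convention
#' under which the four family vectors are defined).  Vectors are in
#' fractional units of the structure's reference cell.
#'
#' @param structure A `"crystal_structure"` with >= 2 layers and
#'   molecule ids (as produced by [build_stack()]).
#' @param tol Maximum allowed residual scatter of the matched
#'   displacements, in fractional units (default 0.01).
#' @return (n_layers - 1) x 3 matrix of fractional vectors (u, v, w).
#' @export
extract_interlayer_vectors <- function(structure, tol = 0.01) {
  stopifnot(inherits(structure, "crystal_structure"))
  ctr <- molecule_centroids(structure)
  if (all(is.na(ctr$layer))) stop("structure carries no layer indices")
  layers <- sort(unique(ctr$layer))
  if (length(layers) < 2) stop("need at least 2 layers to extract vectors")

  rc <- structure$ref_cell
  b_super <- structure$cell$b
  b_ref <- rc$b
  th <- rc$beta * pi / 180
  m2 <- matrix(c(rc$a, 0, rc$c * cos(th), rc$c * sin(th)), 2, 2)

  out <- matrix(NA_real_, length(layers) - 1, 3,
                dimnames = list(NULL, c("u", "v", "w")))
  for (j in seq_len(length(layers) - 1)) {
    p0 <- ctr[ctr$layer == layers[j], ]
    p1 <- ctr[ctr$layer == layers[j + 1], ]
    if (nrow(p0) != nrow(p1))
      stop("rigidity error: layers differ in molecule count")
    # candidate displacements: first molecule of layer k+1 vs all of layer k
    best <- NULL; best_scatter <- Inf
    for (i in seq_len(nrow(p0))) {
      d <- reduce_inplane(p1$x[1] - p0$x[i], p1$z[1] - p0$z[i], m2)
      # residual scatter if this candidate were the rigid translation
      pred_x <- wrap_frac(p0$x + d[1]); pred_z <- wrap_frac(p0$z + d[2])
      resid <- vapply(seq_len(nrow(p1)), function(m) {
        dx <- p1$x[m] - pred_x; dz <- p1$z[m] - pred_z
        dx <- dx - round(dx); dz <- dz - round(dz)
        min(sqrt(dx^2 + dz^2))
      }, numeric(1))
      sc <- max(resid)
      if (sc < best_scatter) { best_scatter <- sc; best <- d }
    }
    if (best_scatter > tol)
      stop(sprintf(
        "rigidity error: matched-displacement scatter %.3g exceeds tolerance %.3g",
        best_scatter, tol))
    dy <- (p1$y[1] - p0$y[1]) * b_super / b_ref   # stacking advance, ref units
    out[j, ] <- c(best[1], dy, best[2])
  }
  out
}

#' Classify interlayer vectors against a stacking family
#'
#' Maps each recovered vector to the nearest family member by in-plane
#' distance (fractional Euclidean on the (u, w) components); vectors
#' further than `tol` from every member are labelled `"X"`.
#'
#' @param vectors Matrix of fractional vectors as from
#'   [extract_interlayer_vectors()].
#' @param family A `"stacking_family"`.
#' @param tol Match tolerance in fractional units (default 0.02).
#' @return A single label string such as `"ABCD"`.
#' @export
classify_sequence <- function(vectors, family, tol = 0.02) {
  if (tol <= 0) stop("tol must be positive")
  if (!is.matrix(vectors)) vectors <- matrix(vectors, ncol = 3)
  fam <- family$vectors
  labs <- vapply(seq_len(nrow(vectors)), function(i) {
    d <- sqrt((fam[, "u"] - vectors[i, 1])^2 +
              (fam[, "w"] - vectors[i, 3])^2)
    j <- which.min(d)
    if (d[j] <= tol) rownames(fam)[j] else "X"
  }, character(1))
  paste(labs, collapse = "")
}
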