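.atomic_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17,
  Ar = 18, K = 19, Ca = 20, Br = 35, I = 53)

# Cromer-Mann 4-Gaussian X-ray form-factor coefficients (International
# Tables vol. C) for the organic elements; optional fidelity switch.
.cromer_mann <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800))

# scattering factors for a vector of elements at sin(theta)/lambda = s
#' @noRd
atomic_f <- function(elements, s = 0, form_factors = "constant") {
  if (identical(form_factors, "constant")) {
    z <- .atomic_numbers[elements]
    if (any(is.na(z)))
      stop("unknown element(s): ",
           paste(unique(elements[is.na(z)]), collapse = ", "))
    return(matrix(z, nrow = length(s), ncol = length(elements), byrow = TRUE))
  }
  out <- matrix(NA_real_, length(s), length(elements))
  for (el in unique(elements)) {
    cm <- .cromer_mann[[el]]
    if (is.null(cm))
      stop("no Cromer-Mann coefficients stored for element ", el)
    f <- cm$c + colSums(cm$a * exp(-outer(cm$b, s^2)))
    out[, elements == el] <- f
  }
  out
}

#' Kinematic structure factor
#'
#' Direct summation F(hkl) = sum_j f_j exp(2 pi i (h x_j + k y_j + l z_j))
#' over all atoms.  By default f_j is the atomic number (a constant):
#' extinction and streaking logic depends on phases, not on the falloff
#' of f.  Setting `form_factors = "cromer_mann"` uses 4-Gaussian X-ray
#' form factors (H, C, N, O).
#'
#' @param structure A `"crystal_structure"`.
#' @param hkl Integer triple or n x 3 matrix of triples.
#' @param form_factors `"constant"` (f = Z) or `"cromer_mann"`.
#' @return Complex amplitude(s), one per row of `hkl`.
#' @examples
#' st <- crystal_structure(cell(5, 5, 5),
#'         data.frame(element = "C", x = 0, y = 0, z = 0))
#' structure_factor(st, c(1, 2, 3))   # 6 + 0i
#' @export
structure_factor <- function(structure, hkl, form_factors = "constant") {
  h <- rbind_hkl(hkl)
  at <- structure$atoms
  xyz <- t(as.matrix(at[, c("x", "y", "z")]))       # 3 x n_atoms
  phase <- exp(2i * pi * (h %*% xyz))               # n_hkl x n_atoms
  if (identical(form_factors, "constant")) {
    f <- as.numeric(.atomic_numbers[at$element])
    if (any(is.na(f)))
      stop("unknown element(s) in structure")
    as.complex(phase %*% f)
  } else {
    s <- 1 / (2 * d_spacing(structure$cell, h))
    fm <- atomic_f(at$element, s, form_factors)     # n_hkl x n_atoms
    as.complex(rowSums(phase * fm))
  }
}

#' Reflection list of a structure
#'
#' Either evaluates the supplied `hkl` set, or enumerates the unique
#' half-sphere (Friedel multiplicity 2, P1 setting) down to a minimum
#' d-spacing.
#'
#' @param structure A `"crystal_structure"`.
#' @param dmin Minimum d-spacing in angstrom (used when `hkl` is NULL).
#' @param hkl Optional explicit n x 3 matrix of indices.
#' @param form_factors Passed to [structure_factor()].
#' @return Data frame with columns `h`, `k`, `l`, `d`, `F2`, `mult`,
#'   of class `"reflection_list"`.
#' @export
reflection_list <- function(structure, dmin = NULL, hkl = NULL,
                            form_factors = "constant") {
  if (is.null(hkl)) {
    if (is.null(dmin) || dmin <= 0)
      stop("supply either dmin > 0 or an explicit hkl set")
    hkl <- enumerate_half_sphere(structure$cell, dmin)
  } else hkl <- rbind_hkl(hkl)
  if (nrow(hkl) == 0) stop("empty reflection set")
  d <- d_spacing(structure$cell, hkl)
  keep <- if (is.null(dmin)) rep(TRUE, length(d)) else d >= dmin
  hkl <- hkl[keep, , drop = FALSE]; d <- d[keep]
  f <- structure_factor(structure, hkl, form_factors)
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    d = d, F2 = Mod(f)^2, mult = 2)
  out$mult[out$h == 0 & out$k == 0 & out$l == 0] <- 1
  class(out) <- c("reflection_list", "data.frame")
  out
}

# unique half-sphere: l > 0, or l = 0 & k > 0, or l = k = 0 & h > 0
#' @noRd
enumerate_half_sphere <- function(cell, dmin) {
  gstar <- solve(metric_tensor(cell))
  hmax <- ceiling(1 / (dmin * sqrt(diag(gstar))))
  g <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                             k = -hmax[2]:hmax[2],
                             l = 0:hmax[3]))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g <- g[keep, , drop = FALSE]
  inv_d2 <- rowSums((g %*% gstar) * g)
  g[inv_d2 <= 1 / dmin^2, , drop = FALSE]
}

#' Check systematic absences against screw-axis / glide conditions
#'
#' Partitions the condition-bearing reflections of a list into
#' satisfying and violating sets using a relative intensity threshold,
#' and returns the violation count plus a consistency verdict.
#' Conditions tested: for P2_1 2_1 2_1, the three screw axes (h00: h
#' even; 0k0: k even; 00l: l even); for P2_1/c, the c glide (h0l: l
#' even) and the 2_1 axis (0k0: k even).
#'
#' @param reflections A `"reflection_list"` (or data frame with h, k, l,
#'   F2).
#' @param rules `"P212121"` or `"P21/c"`.
#' @param eps Relative threshold: a reflection is "absent" when
#'   F2 < eps * max(F2) (default 1e-10).
#' @return List with `rules`, `n_conditioned`, `n_should_be_absent`,
#'   `violations` (data frame), `n_violations`, `consistent`.
#' @export
check_systematic_absences <- function(reflections,
                                      rules = c("P212121", "P21/c"),
                                      eps = 1e-10) {
  rules <- match.arg(rules)
  r <- as.data.frame(reflections)
  if (nrow(r) == 0) stop("empty reflection list")
  odd <- function(x) x %% 2 != 0
  forbidden <- switch(rules,
    "P212121" = (r$k == 0 & r$l == 0 & odd(r$h)) |
                (r$h == 0 & r$l == 0 & odd(r$k)) |
                (r$h == 0 & r$k == 0 & odd(r$l)),
    "P21/c"   = (r$k == 0 & odd(r$l)) |
                (r$h == 0 & r$l == 0 & odd(r$k)))
  conditioned <- switch(rules,
    "P212121" = (r$k == 0 & r$l == 0) | (r$h == 0 & r$l == 0) |
                (r$h == 0 & r$k == 0),
    "P21/c"   = (r$k == 0) | (r$h == 0 & r$l == 0))
  thr <- eps * max(r$F2)
  viol <- r[forbidden & r$F2 >= thr, , drop = FALSE]
  list(rules = rules,
       n_conditioned = sum(conditioned),
       n_should_be_absent = sum(forbidden),
       violations = viol,
       n_violations = nrow(viol),
       consistent = nrow(viol) == 0)
}

# ---------------------------------------------------------------------
# reciprocal rods along the stacking direction

#' @noRd
new_rod_profile <- function(h, l, k, intensity, se = NULL, n_ensemble = 1,
                            meta = list()) {
  if (any(diff(k) <= 0)) stop("rod k grid must be strictly increasing")
  structure(list(h = h, l = l, k = k,
                 intensity = intensity, se = se,
                 n_ensemble = n_ensemble,
                 fwhm = profile_fwhm(k, intensity),
                 meta = meta),
            class = "rod_profile")
}

#' @export
print.rod_profile <- function(x, ...) {
  cat(sprintf("rod profile (h=%d, l=%d): %d k-samples, ensemble %d, FWHM %s r.l.u.\n",
              x$h, x$l, length(x$k), x$n_ensemble,
              if (is.na(x$fwhm)) "n/a" else sprintf("%.4g", x$fwhm)))
  invisible(x)
}

# FWHM of the strongest peak by linear interpolation of half-maximum
# crossings; NA when the profile has no resolved peak
#' @noRd
profile_fwhm <- function(x, y) {
  i <- which.max(y)
  top <- y[i]
  if (!is.finite(top) || top <= 0) return(NA_real_)
  half <- top / 2
  if (min(y) > half) return(NA_real_)      # flat: never falls to half max
  left <- NA_real_
  if (i >= 2) for (j in i:2) if (y[j - 1] <= half) {
    left <- x[j - 1] + (x[j] - x[j - 1]) * (half - y[j - 1]) / (y[j] - y[j - 1])
    break
  }
  right <- NA_real_
  if (i <= length(y) - 1) for (j in i:(length(y) - 1)) if (y[j + 1] <= half) {
    right <- x[j] + (x[j + 1] - x[j]) * (half - y[j]) / (y[j + 1] - y[j])
    break
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

# per-layer in-plane phase factors for a label sequence
#' @noRd
layer_phases <- function(labels, family, h, l) {
  vecs <- family$vectors[labels, , drop = FALSE]
  n <- length(labels)
  cu <- c(0, cumsum(vecs[, "u"]))[seq_len(n)]
  cw <- c(0, cumsum(vecs[, "w"]))[seq_len(n)]
  exp(2i * pi * (h * cu + l * cw))
}

#' Monte-Carlo rod profile from faulted supercells
#'
#' For a rod at fixed in-plane indices (h, l), evaluates the kinematic
#' intensity per layer
#' I(k) = |F_layer(h, l)|^2 |sum_n e^{2 pi i (h u_n + k n v + l w_n)}|^2 / N
#' on a continuous grid of the stacking-axis coordinate k (reciprocal
#' units of the reference cell, so ordered Form II-like stacks peak at
#' integer k), averaged over an ensemble of independently faulted
#' sequences.  The layer form factor uses the motif's in-plane atom
#' positions (planar molecules sit at zero height, so it is
#' k-independent).
#'
#' @param motif A `"layer_motif"`.
#' @param family A `"stacking_family"`.
#' @param base_pattern Ordered base pattern, default `"ABCD"`.
#' @param n_layers Layers per supercell.
#' @param p_fault Fault probability per interface.
#' @param n_ensemble Number of independent supercells averaged.
#' @param h,l Fixed in-plane reflection indices.
#' @param k_samples Strictly increasing numeric grid of k values.
#' @param seed Integer seed for the ensemble.
#' @return A `"rod_profile"` with ensemble mean, standard error and
#'   FWHM of the strongest peak.
#' @export
rod_profile_supercell <- function(motif, family, base_pattern = "ABCD",
                                  n_layers = 200, p_fault = 0,
                                  n_ensemble = 1, h, l,
                                  k_samples = seq(0.5, 1.5, by = 0.002),
                                  seed = 1) {
  if (n_ensemble < 1) stop("n_ensemble must be >= 1")
  at <- motif_atoms(motif)
  f <- as.numeric(.atomic_numbers[at$element])
  f_layer <- sum(f * exp(2i * pi * (h * at$fx + l * at$fz)))
  seqs <- with_seed(seed, {
    member_seeds <- sample.int(.Machine$integer.max, n_ensemble)
    lapply(member_seeds, function(s)
      faulted_sequence(base_pattern, n_layers, p_fault, seed = s))
  })
  nvec <- 0:(n_layers - 1)
  kphase <- exp(2i * pi * family$v * outer(nvec, k_samples))  # N x K
  acc <- matrix(0, n_ensemble, length(k_samples))
  for (m in seq_len(n_ensemble)) {
    e <- layer_phases(seqs[[m]]$labels, family, h, l)
    amp <- as.vector(e %*% kphase)
    acc[m, ] <- Mod(f_layer)^2 * Mod(amp)^2 / n_layers
  }
  mean_i <- colMeans(acc)
  se <- if (n_ensemble > 1)
    apply(acc, 2, stats::sd) / sqrt(n_ensemble) else NULL
  new_rod_profile(h, l, k_samples, mean_i, se, n_ensemble,
                  meta = list(n_layers = n_layers, p_fault = p_fault,
                              base_pattern = base_pattern, seed = seed,
                              f_layer2 = Mod(f_layer)^2))
}

#' Analytic (Hendricks-Teller transfer-matrix) rod profile
#'
#' Closed-form ensemble-average rod intensity for a stack whose labels
#' follow a Markov chain with transition matrix `trans` (rows A, B, C,
#' D summing to 1), started from the stationary distribution.  With
#' per-step phase factors phi_s collected in D = diag(phi), the mean
#' intensity per layer of an N-layer stack is
#' \deqn{I/N = |F|^2 \left(1 + 2 \mathrm{Re} \sum_{m=1}^{N-1}
#'   (1 - m/N)\, \pi^T D (P D)^{m-1} \mathbf{1}\right).}
#' A deterministic cyclic chain reproduces the ordered Bragg comb; an
#' i.i.d. chain (all rows equal) is the fully random fault limit, and is
#' the exact ensemble average of [rod_profile_supercell()] when the
#' substitution process is label-independent (p_fault = 0.75 on any
#' base pattern).
#'
#' @param family A `"stacking_family"`.
#' @param trans 4 x 4 stochastic matrix over labels A, B, C, D.
#' @param h,l Fixed in-plane indices.
#' @param k_samples Strictly increasing k grid.
#' @param n_layers Stack length N entering the finite-size average.
#' @param layer_F2 Squared layer form factor |F(h,l)|^2 (scalar;
#'   default 1, or supply a `"layer_motif"` to compute it).
#' @return A `"rod_profile"` (exact mean, `se = NULL`).
#' @export
rod_profile_analytic <- function(family, trans, h, l,
                                 k_samples = seq(0.5, 1.5, by = 0.002),
                                 n_layers = 200, layer_F2 = 1) {
  trans <- unname(as.matrix(trans))
  if (!all(dim(trans) == c(4, 4)) || any(trans < 0) ||
      any(abs(rowSums(trans) - 1) > 1e-8))
    stop("validation error: transition model rows must be probability distributions over A, B, C, D")
  if (inherits(layer_F2, "layer_motif")) {
    at <- motif_atoms(layer_F2)
    f <- as.numeric(.atomic_numbers[at$element])
    layer_F2 <- Mod(sum(f * exp(2i * pi * (h * at$fx + l * at$fz))))^2
  }
  # stationary distribution of the chain
  ev <- eigen(t(trans))
  i <- which.min(abs(ev$values - 1))
  pi0 <- Re(ev$vectors[, i]); pi0 <- pi0 / sum(pi0)

  fam <- family$vectors[.stack_labels, , drop = FALSE]
  K <- length(k_samples); N <- n_layers
  # per-label phase, 4 x K (v advance common to all labels)
  dmat <- exp(2i * pi * (outer(h * fam[, "u"] + l * fam[, "w"], rep(1, K)) +
                         outer(rep(family$v, 4), k_samples)))
  r <- dmat * pi0                                  # pi^T D, kept as 4 x K
  csum <- rep(0 + 0i, K)
  tp <- t(trans)
  for (m in seq_len(N - 1)) {
    csum <- csum + (1 - m / N) * colSums(r)
    if (m < N - 1) r <- (tp %*% r) * dmat          # advance (PD)^m
  }
  intensity <- layer_F2 * (1 + 2 * Re(csum))
  intensity[intensity < 0] <- 0                    # guard tiny roundoff
  new_rod_profile(h, l, k_samples, intensity, NULL, 1,
                  meta = list(n_layers = n_layers, model = "transfer-matrix"))
}

#' Transition matrix of a deterministic cyclic stacking pattern
#'
#' @param pattern Label string such as `"ABCD"` or `"AB"`.
#' @return 4 x 4 stochastic matrix cycling through the pattern.
#' @export
cyclic_transition_matrix <- function(pattern) {
  p <- check_labels(pattern)
  m <- matrix(0, 4, 4, dimnames = list(.stack_labels, .stack_labels))
  n <- length(p)
  for (i in seq_len(n)) m[p[i], p[i %% n + 1]] <- 1
  # labels never visited: make them self-absorbing so rows stay stochastic
  for (s in .stack_labels) if (sum(m[s, ]) == 0) m[s, s] <- 1
  m
}

#' Streak metric: FWHM ratio of two rod profiles
#'
#' FWHM of the strongest peak of `rod` divided by that of `reference`
#' (typically the ordered model): about 1 means sharp, > 1 streaked.
#'
#' @param rod,reference `"rod_profile"` objects on the same k grid.
#' @return Ratio, or `NA` (with a warning) when either profile is flat.
#' @export
streak_metric <- function(rod, reference) {
  if (length(rod$k) != length(reference$k) ||
      max(abs(rod$k - reference$k)) > 1e-9)
    stop("rod profiles must share the same k grid")
  if (is.na(rod$fwhm) || is.na(reference$fwhm)) {
    warning("no resolved peak in at least one profile; returning NA")
    return(NA_real_)
  }
  rod$fwhm / reference$fwhm
}

# ---------------------------------------------------------------------
# powder patterns

#' Powder diffraction pattern container
#'
#' @param two_theta Strictly increasing 2-theta grid, degrees.
#' @param intensity Intensity array.
#' @param wavelength Wavelength in angstrom.
#' @param weights Optional per-point least-squares weights.
#' @param sigma Optional per-point standard deviations.
#' @param meta Optional named list.
#' @return An object of class `"powder_pattern"`.
#' @export
powder_pattern_object <- function(two_theta, intensity,
                                  wavelength = 0.82408,
                                  weights = NULL, sigma = NULL,
                                  meta = list()) {
  if (any(diff(two_theta) <= 0))
    stop("2-theta grid must be strictly increasing")
  if (length(intensity) != length(two_theta))
    stop("intensity and grid lengths differ")
  if (wavelength <= 0) stop("wavelength must be positive")
  structure(list(two_theta = two_theta, intensity = intensity,
                 wavelength = wavelength, weights = weights,
                 sigma = sigma, meta = meta),
            class = "powder_pattern")
}

#' @export
print.powder_pattern <- function(x, ...) {
  cat(sprintf("powder pattern: %d points, 2theta %.3f..%.3f deg, lambda %.5f A\n",
              length(x$two_theta), min(x$two_theta), max(x$two_theta),
              x$wavelength))
  invisible(x)
}

# area-normalized pseudo-Voigt profile centred at 0
#' @noRd
pseudo_voigt <- function(x, fwhm, eta) {
  g <- 2 / fwhm * sqrt(log(2) / pi) * exp(-4 * log(2) * (x / fwhm)^2)
  l <- 2 / (pi * fwhm) / (1 + 4 * (x / fwhm)^2)
  eta * l + (1 - eta) * g
}

#' Bragg stick list of a structure for a powder experiment
#'
#' Enumerates reflections reachable within the 2-theta range and
#' returns stick positions and integrated intensities
#' (|F|^2 x multiplicity x optional Lorentz factor 1/(sin^2 theta cos
#' theta)).
#'
#' @param structure A `"crystal_structure"` or a list of them (ensemble;
#'   stick intensities are averaged — cells must agree).
#' @param wavelength Wavelength in angstrom.
#' @param two_theta_range Length-2 numeric, degrees.
#' @param lorentz Apply the Lorentz factor (default TRUE).
#' @param form_factors Passed to [structure_factor()].
#' @return Data frame `h`, `k`, `l`, `d`, `two_theta`, `intensity`.
#' @export
powder_sticks <- function(structure, wavelength = 0.82408,
                          two_theta_range = c(2, 30), lorentz = TRUE,
                          form_factors = "constant") {
  members <- if (inherits(structure, "crystal_structure"))
    list(structure) else structure
  stopifnot(length(members) >= 1)
  smax <- sin(max(two_theta_range) / 2 * pi / 180)
  if (smax <= 0) stop("empty pattern: 2-theta range collapses")
  dmin <- wavelength / (2 * smax)
  refl <- reflection_list(members[[1]], dmin = dmin,
                          form_factors = form_factors)
  f2 <- refl$F2
  if (length(members) > 1) {
    for (m in 2:length(members)) {
      rm_ <- reflection_list(members[[m]], dmin = dmin,
                             form_factors = form_factors)
      if (nrow(rm_) != nrow(refl))
        stop("ensemble members must share the same cell (stick grids differ)")
      f2 <- f2 + rm_$F2
    }
    f2 <- f2 / length(members)
  }
  sin_th <- wavelength / (2 * refl$d)
  keep <- sin_th <= 1
  refl <- refl[keep, , drop = FALSE]; f2 <- f2[keep]
  sin_th <- sin_th[keep]
  th <- asin(sin_th)
  tt <- 2 * th * 180 / pi
  inten <- f2 * refl$mult
  if (lorentz) inten <- inten / (sin_th^2 * cos(th))
  keep <- tt >= min(two_theta_range) & tt <= max(two_theta_range)
  out <- data.frame(h = refl$h[keep], k = refl$k[keep], l = refl$l[keep],
                    d = refl$d[keep], two_theta = tt[keep],
                    intensity = inten[keep])
  if (nrow(out) == 0) stop("empty pattern: no reflections in range")
  out[order(out$two_theta), ]
}

# convolve sticks with a pseudo-Voigt onto a grid
#' @noRd
profile_from_sticks <- function(sticks, grid, fwhm, eta, zero = 0) {
  y <- numeric(length(grid))
  win <- 12 * fwhm
  pos <- sticks$two_theta + zero
  for (i in seq_len(nrow(sticks))) {
    j <- which(abs(grid - pos[i]) <= win)
    if (length(j))
      y[j] <- y[j] + sticks$intensity[i] * pseudo_voigt(grid[j] - pos[i],
                                                        fwhm, eta)
  }
  y
}

#' Simulate a powder pattern
#'
#' Kinematic powder pattern of one structure or an ensemble average
#' (e.g. independently faulted supercells): Bragg sticks from
#' [powder_sticks()] convolved with a pseudo-Voigt profile.
#'
#' @inheritParams powder_sticks
#' @param step 2-theta step in degrees.
#' @param fwhm Pseudo-Voigt full width at half maximum, degrees
#'   (default 0.05).
#' @param eta Lorentzian fraction of the pseudo-Voigt (default 0.5).
#' @return A `"powder_pattern"`.
#' @export
powder_pattern <- function(structure, wavelength = 0.82408,
                           two_theta_range = c(2, 30), step = 0.01,
                           fwhm = 0.05, eta = 0.5, lorentz = TRUE,
                           form_factors = "constant") {
  if (step <= 0) stop("step must be positive")
  if (min(two_theta_range) <= 0 || max(two_theta_range) >= 180)
    stop("2-theta range must lie within (0, 180) degrees")
  sticks <- powder_sticks(structure, wavelength, two_theta_range,
                          lorentz, form_factors)
  grid <- seq(min(two_theta_range), max(two_theta_range), by = step)
  y <- profile_from_sticks(sticks, grid, fwhm, eta)
  powder_pattern_object(grid, y, wavelength,
                        meta = list(fwhm = fwhm, eta = eta,
                                    lorentz = lorentz,
                                    n_members = if (inherits(structure, "crystal_structure")) 1
                                                else length(structure)))
}
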