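#' Poisson-noised powder pattern
#'
#' Counting-statistics fixture generator: adds a polynomial background
#' (raw coefficients in 2-theta), scales to counts and draws Poisson
#' variates per point.  Per-point sigma and least-squares weights
#' (1/max(counts, 1)) are recorded, so goodness-of-fit statistics keep
#' their counting-statistics interpretation.
#'
#' @param pattern A `"powder_pattern"` holding the noise-free signal.
#' @param background Polynomial coefficients c(b0, b1, ...) evaluated on
#'   the 2-theta grid (default 0).
#' @param count_scale Counts per intensity unit (> 0).
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A `"powder_pattern"` in counts, with `sigma` and `weights`.
#' @export
make_noisy_pattern <- function(pattern, background = 0, count_scale = 1,
                               seed = 1) {
  stopifnot(inherits(pattern, "powder_pattern"))
  if (count_scale <= 0) stop("count_scale must be positive")
  bg <- polynomial_background(background, pattern$two_theta)
  if (any(bg < 0))
    stop("invalid background: negative at some grid points")
  lambda <- count_scale * (pattern$intensity + bg)
  counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
  powder_pattern_object(pattern$two_theta, counts, pattern$wavelength,
                        weights = 1 / pmax(counts, 1),
                        sigma = sqrt(pmax(counts, 1)),
                        meta = c(pattern$meta,
                                 list(count_scale = count_scale,
                                      seed = seed,
                                      background = background)))
}

#' @noRd
polynomial_background <- function(coefs, x) {
  y <- numeric(length(x))
  for (i in seq_along(coefs)) y <- y + coefs[i] * x^(i - 1)
  y
}

#' Weighted profile residual Rwp
#'
#' Rwp = 100 sqrt( sum w (y_obs - y_calc)^2 / sum w y_obs^2 ), the
#' standard figure of merit for powder-profile fits.
#'
#' @param obs,calc `"powder_pattern"` objects on the same grid.
#' @param weights Optional weights; defaults to the observed pattern's
#'   stored weights, else 1/max(y_obs, 1).
#' @return Rwp in percent.
#' @export
r_wp <- function(obs, calc, weights = NULL) {
  check_same_grid(obs, calc)
  w <- resolve_weights(obs, weights)
  100 * sqrt(sum(w * (obs$intensity - calc$intensity)^2) /
             sum(w * obs$intensity^2))
}

#' Expected residual Rexp
#'
#' Rexp = 100 sqrt( (N - P) / sum w y_obs^2 ): the statistically
#' expected value of Rwp for a model that is exact up to counting
#' noise; the companion of Rwp in the goodness of fit.
#'
#' @param obs A `"powder_pattern"`.
#' @param weights Optional weights (default as in [r_wp()]).
#' @param n_params Number of refined parameters P.
#' @return Rexp in percent.
#' @export
r_exp <- function(obs, weights = NULL, n_params = 0) {
  n <- length(obs$two_theta)
  if (n <= n_params)
    stop("degrees-of-freedom error: need more points than parameters")
  w <- resolve_weights(obs, weights)
  100 * sqrt((n - n_params) / sum(w * obs$intensity^2))
}

#' Goodness of fit
#'
#' GooF = Rwp / Rexp; 1 is the counting-statistics ideal.
#'
#' @param rwp,rexp Residuals in percent.
#' @return Ratio.
#' @export
goof <- function(rwp, rexp) {
  if (rexp <= 0) stop("division error: Rexp must be positive")
  rwp / rexp
}

#' @noRd
check_same_grid <- function(a, b) {
  if (length(a$two_theta) != length(b$two_theta) ||
      max(abs(a$two_theta - b$two_theta)) > 1e-9)
    stop("alignment error: patterns are on different 2-theta grids")
}

#' @noRd
resolve_weights <- function(obs, weights) {
  if (!is.null(weights)) return(weights)
  if (!is.null(obs$weights)) return(obs$weights)
  1 / pmax(obs$intensity, 1)
}

#' Profile-fit model: phases plus profile/background parameters
#'
#' "Rietveld-style" here means fixed atomic models: only scale factors,
#' a zero shift, a Chebyshev background and a global peak width are
#' refined, which is what the ordered-versus-faulted model comparison
#' needs.
#'
#' @param phases One phase or a list of phases, each either a
#'   `"crystal_structure"` / list of structures (ensemble) or a
#'   precomputed stick data frame from [powder_sticks()].
#' @param scale Starting scale factor(s), recycled over phases.
#' @param zero Starting zero shift in degrees 2-theta.
#' @param bg_degree Chebyshev background degree (default 3).
#' @param fwhm Starting pseudo-Voigt FWHM in degrees.
#' @param eta Lorentzian fraction (fixed during the fit).
#' @return An object of class `"fit_model"`.
#' @export
fit_model <- function(phases, scale = 1, zero = 0, bg_degree = 3,
                      fwhm = 0.05, eta = 0.5) {
  if (inherits(phases, "crystal_structure") || is.data.frame(phases))
    phases <- list(phases)
  if (length(phases) < 1) stop("at least one phase is required")
  structure(list(phases = phases,
                 scale = rep_len(scale, length(phases)),
                 zero = zero, bg_degree = bg_degree,
                 fwhm = fwhm, eta = eta),
            class = "fit_model")
}

# Chebyshev design matrix on [-1, 1] mapped from the 2-theta range
#' @noRd
chebyshev_basis <- function(x, degree) {
  t <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  m <- matrix(0, length(x), degree + 1)
  m[, 1] <- 1
  if (degree >= 1) m[, 2] <- t
  if (degree >= 2) for (j in 3:(degree + 1)) m[, j] <- 2 * t * m[, j - 1] - m[, j - 2]
  m
}

#' Least-squares profile fit of a powder pattern
#'
#' Minimizes sum w (y_obs - y_calc)^2 over per-phase scales, zero shift,
#' Chebyshev background coefficients and a global peak FWHM, with fixed
#' atomic models.  Linear parameters (scales, background) are solved
#' exactly by weighted least squares at every trial of the nonlinear
#' pair (zero, fwhm), which is driven by bounded L-BFGS-B; scales are
#' clipped at zero.  Deterministic for identical inputs and starting
#' values.
#'
#' @param obs Observed `"powder_pattern"` (weights taken from it, or
#'   1/max(y, 1)).
#' @param model A `"fit_model"`.
#' @param refine_zero,refine_fwhm Refine the nonlinear parameters
#'   (default TRUE).
#' @param zero_limit Bound on |zero shift| in degrees (default 0.5).
#' @param max_iter Iteration budget for the optimizer.
#' @return A `"fit_result"`: `rwp`, `rexp`, `goof` (consistent by
#'   construction), refined `scales`, `zero`, `fwhm`, `background`,
#'   `scale_se` (from the weighted normal equations), `converged`,
#'   `residuals`, `calc` (the fitted pattern).
#' @export
fit_pattern <- function(obs, model, refine_zero = TRUE,
                        refine_fwhm = TRUE, zero_limit = 0.5,
                        max_iter = 200) {
  stopifnot(inherits(obs, "powder_pattern"), inherits(model, "fit_model"))
  grid <- obs$two_theta
  w <- resolve_weights(obs, NULL)
  y <- obs$intensity
  rng <- range(grid)

  sticks <- lapply(model$phases, function(p) {
    if (is.data.frame(p)) p
    else powder_sticks(p, obs$wavelength, rng)
  })
  np <- length(sticks)
  # normalize stick intensities so the design matrix is well conditioned;
  # reported scales refer to the phases as supplied
  stick_norm <- vapply(sticks, function(s) max(s$intensity), numeric(1))
  stick_norm[stick_norm <= 0] <- 1
  for (i in seq_len(np)) sticks[[i]]$intensity <- sticks[[i]]$intensity / stick_norm[i]
  cheb <- chebyshev_basis(grid, model$bg_degree)

  design <- function(zero, fwhm) {
    cols <- vapply(sticks, function(s)
      profile_from_sticks(s, grid, fwhm, model$eta, zero),
      numeric(length(grid)))
    cbind(cols, cheb)
  }
  solve_linear <- function(x) {
    xtwx <- crossprod(x * sqrt(w))
    beta <- tryCatch(solve(xtwx, crossprod(x, w * y)),
                     error = function(e) rep(0, ncol(x)))
    beta <- as.numeric(beta)
    neg <- which(beta[seq_len(np)] < 0)
    if (length(neg)) {           # re-solve with offending scales pinned at 0
      keep <- setdiff(seq_len(ncol(x)), neg)
      sub <- tryCatch(solve(crossprod(x[, keep, drop = FALSE] * sqrt(w)),
                            crossprod(x[, keep, drop = FALSE], w * y)),
                      error = function(e) rep(0, length(keep)))
      beta <- numeric(ncol(x)); beta[keep] <- as.numeric(sub)
    }
    beta
  }
  objective <- function(par) {
    zero <- if (refine_zero) par[1] else model$zero
    fwhm <- if (refine_fwhm) par[length(par)] else model$fwhm
    x <- design(zero, fwhm)
    beta <- solve_linear(x)
    sum(w * (y - as.numeric(x %*% beta))^2)
  }

  par0 <- c(if (refine_zero) model$zero,
            if (refine_fwhm) model$fwhm)
  converged <- TRUE
  if (length(par0)) {
    lower <- c(if (refine_zero) -zero_limit,
               if (refine_fwhm) 1e-3)
    upper <- c(if (refine_zero) zero_limit,
               if (refine_fwhm) 2)
    f0 <- objective(par0)
    opt <- stats::optim(par0, objective, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = max_iter))
    # L-BFGS-B reports an abnormal line search when the start is already
    # at the optimum (e.g. a noise-free self-fit); that is convergence
    converged <- opt$convergence == 0 ||
      (opt$convergence > 1 && opt$value <= f0 + 1e-12 * (1 + abs(f0)))
    zero <- if (refine_zero) opt$par[1] else model$zero
    fwhm <- if (refine_fwhm) opt$par[length(opt$par)] else model$fwhm
  } else {
    zero <- model$zero; fwhm <- model$fwhm
  }

  x <- design(zero, fwhm)
  beta <- solve_linear(x)
  ycalc <- as.numeric(x %*% beta)
  calc <- powder_pattern_object(grid, ycalc, obs$wavelength)
  n_params <- np + (model$bg_degree + 1) +
    as.integer(refine_zero) + as.integer(refine_fwhm)
  rwp <- r_wp(obs, calc, w)
  rexp <- r_exp(obs, w, n_params)
  # parameter covariance from the weighted normal equations (counting
  # weights make this the Fisher approximation)
  cov <- tryCatch(solve(crossprod(x * sqrt(w))), error = function(e) NULL)
  scale_se <- if (is.null(cov)) rep(NA_real_, np)
              else sqrt(pmax(diag(cov)[seq_len(np)], 0))
  structure(list(rwp = rwp, rexp = rexp, goof = goof(rwp, rexp),
                 scales = beta[seq_len(np)] / stick_norm,
                 scale_se = scale_se / stick_norm,
                 background = beta[-seq_len(np)],
                 zero = zero, fwhm = fwhm, eta = model$eta,
                 n_params = n_params,
                 converged = converged,
                 residuals = y - ycalc,
                 calc = calc),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("profile fit: Rwp = %.3f%%, Rexp = %.3f%%, GooF = %.3f%s\n",
              x$rwp, x$rexp, x$goof,
              if (x$converged) "" else "  [NOT converged]"))
  cat(sprintf("  scales: %s; zero = %+.4f deg; FWHM = %.4f deg\n",
              paste(sprintf("%.4g", x$scales), collapse = ", "),
              x$zero, x$fwhm))
  invisible(x)
}

#' Fit several models and rank them by Rwp
#'
#' Mirrors the ordered-versus-faulted supercell comparison: each model
#' is fitted to the same observation and results are returned sorted by
#' Rwp (best first).
#'
#' @param obs Observed `"powder_pattern"`.
#' @param models List of at least two `"fit_model"` objects (named list
#'   names are carried into the table).
#' @param ... Passed to [fit_pattern()].
#' @return List with `table` (data frame: model, rwp, rexp, goof,
#'   converged, ordered by rwp) and `results` (fit results in the same
#'   order).
#' @export
compare_models <- function(obs, models, ...) {
  if (!is.list(models) || length(models) < 2)
    stop("compare_models needs at least two models")
  nm <- names(models)
  if (is.null(nm)) nm <- paste0("model", seq_along(models))
  fits <- lapply(models, fit_pattern, obs = obs, ...)
  ord <- order(vapply(fits, `[[`, numeric(1), "rwp"))
  tab <- data.frame(model = nm[ord],
                    rwp = vapply(fits[ord], `[[`, numeric(1), "rwp"),
                    rexp = vapply(fits[ord], `[[`, numeric(1), "rexp"),
                    goof = vapply(fits[ord], `[[`, numeric(1), "goof"),
                    converged = vapply(fits[ord], `[[`, logical(1), "converged"))
  list(table = tab, results = fits[ord])
}
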