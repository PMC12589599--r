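make_peaky_pattern <- function(grid = seq(5, 15, by = 0.02)) {
  y <- 0.8 * exp(-((grid - 7) / 0.05)^2) + 1.0 * exp(-((grid - 11) / 0.05)^2)
  powder_pattern_object(grid, y, 0.82408)
}

test_that("Rwp behaves per its definition", {
  obs <- make_peaky_pattern()
  expect_equal(r_wp(obs, obs), 0)
  zero <- powder_pattern_object(obs$two_theta, 0 * obs$intensity, 0.82408)
  expect_equal(r_wp(obs, zero, weights = rep(1, length(obs$two_theta))), 100)
  other <- powder_pattern_object(obs$two_theta + 0.5, obs$intensity, 0.82408)
  expect_error(r_wp(obs, other), "alignment")
})

test_that("Rexp matches its closed form and scaling", {
  n <- 50
  obs <- powder_pattern_object(seq_len(n), rep(4, n), 1)
  w1 <- rep(1, n)
  expect_equal(r_exp(obs, w1, 0), 100 / 4 / sqrt(1), tolerance = 1e-12)
  obs2 <- powder_pattern_object(seq_len(n), rep(8, n), 1)
  expect_equal(r_exp(obs2, w1, 0), r_exp(obs, w1, 0) / 2, tolerance = 1e-12)
  expect_error(r_exp(obs, w1, n), "degrees-of-freedom")
})

test_that("GooF is the Rwp/Rexp ratio", {
  expect_equal(goof(2.36, 1.0), 2.36)
  expect_equal(goof(3, 3), 1)
  expect_equal(goof(1.55, 0.63), 2.46, tolerance = 0.01)
  expect_error(goof(1, 0), "division")
})

test_that("counting statistics drive GooF to 1 for a true model", {
  base <- make_peaky_pattern()
  obs <- make_noisy_pattern(base, background = 0.05, count_scale = 1e6,
                            seed = 21)
  calc <- powder_pattern_object(base$two_theta,
                                1e6 * (base$intensity + 0.05),
                                base$wavelength)
  g <- goof(r_wp(obs, calc), r_exp(obs, n_params = 0))
  expect_lt(abs(g - 1), 0.1)
})

test_that("a noise-free self-fit is essentially exact", {
  fam <- default_family()
  st <- build_stack(tiny_motif(), periodic_sequence("ABCD", 4), fam)
  pp <- powder_pattern(st, two_theta_range = c(3, 14), step = 0.01)
  scale0 <- 1 / max(pp$intensity)
  obs <- powder_pattern_object(pp$two_theta, pp$intensity * scale0,
                               pp$wavelength)
  fit <- fit_pattern(obs, fit_model(st, bg_degree = 1))
  expect_lt(fit$rwp, 0.01)
  expect_equal(fit$scales[1], scale0, tolerance = 1e-3)
  expect_lt(abs(fit$zero), 1e-4)
  expect_true(fit$converged)
})

test_that("two-phase scale ratios are recovered within statistical error", {
  fam <- default_family()
  stA <- build_stack(tiny_motif(seed = 2), periodic_sequence("ABCD", 4), fam)
  stB <- build_stack(make_layer_motif(hex_mol(), 2, footprint = c(8.3, 12.1, 90),
                                      layer_spacing = 3.4, seed = 5),
                     periodic_sequence("ABCD", 4), fam)
  ppA <- powder_pattern(stA, two_theta_range = c(3, 14), step = 0.01)
  ppB <- powder_pattern(stB, two_theta_range = c(3, 14), step = 0.01)
  norm <- max(ppA$intensity)
  truth <- 0.5
  mix <- powder_pattern_object(ppA$two_theta,
                               (ppA$intensity + truth * ppB$intensity) / norm,
                               ppA$wavelength)
  obs <- make_noisy_pattern(mix, background = 20, count_scale = 2e4, seed = 31)
  fit <- fit_pattern(obs, fit_model(list(stA, stB), bg_degree = 2))
  ratio <- fit$scales[2] / fit$scales[1]
  se_ratio <- ratio * sqrt((fit$scale_se[1] / fit$scales[1])^2 +
                           (fit$scale_se[2] / fit$scales[2])^2)
  expect_lt(abs(ratio - truth), 3 * se_ratio)
  expect_lt(abs(ratio - truth), 0.05)       # and close in absolute terms
})

test_that("zero-shift recovery is unbiased over replicates", {
  base <- make_peaky_pattern()
  st <- build_stack(tiny_motif(), periodic_sequence("ABCD", 4),
                    default_family())
  pp <- powder_pattern(st, two_theta_range = c(3, 14), step = 0.01)
  scale0 <- 1 / max(pp$intensity)
  shifted_sticks <- powder_sticks(st, pp$wavelength, c(3, 14))
  shifted_sticks$two_theta <- shifted_sticks$two_theta + 0.02
  truth_pattern <- powder_pattern_object(
    pp$two_theta,
    polystack:::profile_from_sticks(shifted_sticks, pp$two_theta, 0.05, 0.5) * scale0,
    pp$wavelength)
  zs <- vapply(1:20, function(s) {
    obs <- make_noisy_pattern(truth_pattern, background = 0.01,
                              count_scale = 2e4, seed = s)
    fit_pattern(obs, fit_model(st, bg_degree = 1))$zero
  }, numeric(1))
  expect_lt(abs(mean(zs) - 0.02), 0.005)
})

test_that("model ranking puts the generating model first", {
  fam <- default_family()
  stA <- build_stack(tiny_motif(seed = 2), periodic_sequence("ABCD", 4), fam)
  stB <- build_stack(make_layer_motif(hex_mol(), 2, footprint = c(8.3, 12.1, 90),
                                      layer_spacing = 3.4, seed = 5),
                     periodic_sequence("ABCD", 4), fam)
  ppA <- powder_pattern(stA, two_theta_range = c(3, 14), step = 0.01)
  obs <- make_noisy_pattern(
    powder_pattern_object(ppA$two_theta, ppA$intensity / max(ppA$intensity),
                          ppA$wavelength),
    background = 5, count_scale = 1e4, seed = 3)
  cmp <- compare_models(obs, list(self = fit_model(stA),
                                  wrong = fit_model(stB)))
  expect_equal(cmp$table$model[1], "self")
  expect_lt(cmp$table$rwp[1], cmp$table$rwp[2])
  expect_error(compare_models(obs, list(fit_model(stA))), "at least two")
})
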