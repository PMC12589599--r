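# rod coordinates are in reciprocal units of the Form II-like reference
# cell: in-plane rods (h != 0) peak at integer k, while the strong
# systematic row through the origin (h = l = 0) peaks at the layer
# repeat k = 4m because the flat layers are identical.

test_that("the ordered stack gives a finite-size-limited Bragg comb", {
  motif <- tiny_motif()
  fam <- default_family()
  k <- seq(0.5, 1.5, by = 0.001)
  rod <- rod_profile_supercell(motif, fam, "ABCD", n_layers = 20,
                               p_fault = 0, n_ensemble = 1,
                               h = 1, l = 0, k_samples = k, seed = 1)
  # a 20-layer comb has only 5 periods, so the slowly varying 4-layer
  # structure factor can pull the maximum slightly off the Bragg point
  expect_lt(abs(rod$k[which.max(rod$intensity)] - 1), 0.05)
  # FWHM of a perfect N-layer comb ~ 0.886 / (N v)
  expect_lt(rod$fwhm, 2 * 0.886 / (20 * 0.25))
  expect_true(all(rod$intensity >= 0))
})

test_that("the h = l = 0 rod is blind to in-plane faulting", {
  motif <- tiny_motif()
  fam <- default_family()
  k <- seq(3.5, 4.5, by = 0.002)
  r0 <- rod_profile_supercell(motif, fam, "ABCD", 50, 0, 1,
                              h = 0, l = 0, k_samples = k, seed = 1)
  r5 <- rod_profile_supercell(motif, fam, "ABCD", 50, 0.5, 4,
                              h = 0, l = 0, k_samples = k, seed = 99)
  expect_equal(r5$intensity, r0$intensity, tolerance = 1e-9)
  expect_equal(streak_metric(r5, r0), 1, tolerance = 1e-9)
})

test_that("faulting streaks in-plane rods and the ratio grows with p_fault", {
  motif <- tiny_motif()
  fam <- default_family()
  k <- seq(0.5, 1.5, by = 0.002)
  ref <- rod_profile_supercell(motif, fam, "ABCD", 100, 0, 1,
                               h = 1, l = 0, k_samples = k, seed = 1)
  expect_equal(streak_metric(ref, ref), 1)
  ratios <- vapply(c(0.1, 0.2, 0.3), function(p) {
    rod <- rod_profile_supercell(motif, fam, "ABCD", 100, p, 100,
                                 h = 1, l = 0, k_samples = k, seed = 7)
    streak_metric(rod, ref)
  }, numeric(1))
  expect_gt(ratios[3], 1.5)
  expect_true(all(diff(ratios) > 0))       # monotone in p_fault
})

test_that("intensity is conserved along a rod as faults redistribute it", {
  motif <- tiny_motif()
  fam <- default_family()
  n <- 64
  k <- seq(0, 4, length.out = 129)[-129]   # one reciprocal period, M > N
  base <- rod_profile_supercell(motif, fam, "ABCD", n, 0, 1,
                                h = 1, l = 0, k_samples = k, seed = 1)
  for (p in c(0.2, 0.6)) {
    rod <- rod_profile_supercell(motif, fam, "ABCD", n, p, 1,
                                 h = 1, l = 0, k_samples = k, seed = 5)
    expect_equal(mean(rod$intensity), mean(base$intensity),
                 tolerance = 1e-9)
  }
})

test_that("the transfer-matrix profile reproduces the ordered and random limits", {
  fam <- default_family()
  k <- seq(0.5, 1.5, by = 0.002)
  comb <- rod_profile_analytic(fam, cyclic_transition_matrix("ABCD"),
                               h = 1, l = 0, k_samples = k, n_layers = 100)
  expect_lt(abs(comb$k[which.max(comb$intensity)] - 1), 0.01)
  expect_lt(comb$fwhm, 2 * 0.886 / (100 * 0.25))
  # i.i.d. labels: smooth profile, no Bragg comb
  iid <- rod_profile_analytic(fam, matrix(1 / 4, 4, 4),
                              h = 1, l = 0, k_samples = k, n_layers = 100)
  expect_lt(max(iid$intensity) / max(min(iid$intensity), 1e-12), 50)
  expect_lt(max(iid$intensity) / max(comb$intensity), 0.2)
  expect_error(rod_profile_analytic(fam, matrix(1, 4, 4), 1, 0),
               "probability distributions")
})

test_that("supercell Monte-Carlo agrees with the transfer-matrix oracle", {
  motif <- tiny_motif()
  fam <- default_family()
  k <- seq(0.5, 1.5, by = 0.005)
  # p_fault = 0.75 makes the substitution process exactly i.i.d. uniform
  mc <- rod_profile_supercell(motif, fam, "ABCD", 100, 0.75, 200,
                              h = 1, l = 0, k_samples = k, seed = 13)
  an <- rod_profile_analytic(fam, matrix(1 / 4, 4, 4), h = 1, l = 0,
                             k_samples = k, n_layers = 100,
                             layer_F2 = motif)
  z <- (mc$intensity - an$intensity) / mc$se
  expect_gte(mean(abs(z) <= 3), 0.99)
  expect_lt(max(abs(z)), 6)
})

test_that("flat rods yield an NA streak ratio with a warning", {
  motif <- tiny_motif()
  fam <- default_family()
  k <- seq(0.5, 1.5, by = 0.01)
  flat <- rod_profile_supercell(motif, fam, "ABCD", 50, 0, 1,
                                h = 0, l = 0, k_samples = k, seed = 1)
  ref <- rod_profile_supercell(motif, fam, "ABCD", 50, 0, 1,
                               h = 1, l = 0, k_samples = k, seed = 1)
  expect_warning(ratio <- streak_metric(flat, ref), "no resolved peak")
  expect_true(is.na(ratio))
})
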