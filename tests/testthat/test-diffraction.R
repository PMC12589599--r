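test_that("structure factors follow the kinematic sum", {
  cl <- cell(5, 5, 5)
  one <- crystal_structure(cl, data.frame(element = "C", x = 0, y = 0, z = 0))
  f <- structure_factor(one, rbind(c(1, 2, 3), c(0, 0, 1), c(5, 0, 0)))
  expect_equal(f, rep(6 + 0i, 3), tolerance = 1e-12)
  # antiphase pair cancels odd-sum reflections
  two <- crystal_structure(cl, data.frame(element = c("C", "C"),
                                          x = c(0, 0.5), y = c(0, 0.5),
                                          z = c(0, 0.5)))
  expect_equal(Mod(structure_factor(two, c(1, 1, 1))), 0, tolerance = 1e-12)
  expect_equal(Mod(structure_factor(two, c(2, 0, 0))), 12, tolerance = 1e-12)
})

test_that("Friedel pairs have equal intensity for real scattering factors", {
  set.seed(3)
  cl <- cell(8, 9, 11)
  st <- crystal_structure(cl, data.frame(element = sample(c("C", "N", "O"), 15, TRUE),
                                         x = runif(15), y = runif(15),
                                         z = runif(15)))
  hkl <- as.matrix(expand.grid(h = -2:2, k = -2:2, l = 1:2))
  f2p <- Mod(structure_factor(st, hkl))^2
  f2m <- Mod(structure_factor(st, -hkl))^2
  expect_equal(f2p, f2m, tolerance = 1e-12)
})

test_that("Cromer-Mann form factors reduce towards Z at zero angle and fall off", {
  cl <- cell(20, 20, 20)
  st <- crystal_structure(cl, data.frame(element = "O", x = 0, y = 0, z = 0))
  f_low <- Mod(structure_factor(st, c(1, 0, 0), form_factors = "cromer_mann"))
  f_high <- Mod(structure_factor(st, c(18, 0, 0), form_factors = "cromer_mann"))
  expect_equal(f_low, 8, tolerance = 0.02)
  expect_lt(f_high, f_low)
})

test_that("d-spacings come from the metric tensor", {
  expect_equal(d_spacing(cell(2, 2, 2), c(1, 0, 0)), 2, tolerance = 1e-12)
  expect_equal(d_spacing(form_ii_cell(), c(0, 1, 0)), 12.54, tolerance = 1e-12)
  # orthorhombic closed form for (110)
  cl <- cell(6, 8, 10)
  expect_equal(d_spacing(cl, c(1, 1, 0)), 1 / sqrt(1 / 36 + 1 / 64),
               tolerance = 1e-12)
  expect_error(d_spacing(cl, c(0, 0, 0)), "undefined")
})

test_that("systematic-absence verdicts separate P212121 from P1 models", {
  cl <- cell(9, 11, 13)
  for (seed in 1:10) {
    set.seed(seed)
    st <- expand_symmetry(matrix(runif(9), 3), symmetry_ops("P212121"), cl)
    chk <- check_systematic_absences(reflection_list(st, hkl = axial_hkl(8)),
                                     "P212121")
    expect_true(chk$consistent)
    expect_equal(chk$n_violations, 0)
    stp1 <- expand_symmetry(matrix(runif(9), 3), symmetry_ops("P1"), cl)
    chk1 <- check_systematic_absences(reflection_list(stp1, hkl = axial_hkl(8)),
                                      "P212121")
    expect_gt(chk1$n_violations, 0)
    expect_false(chk1$consistent)
  }
  # P21/c: c-glide kills h0l with odd l
  set.seed(1)
  stc <- expand_symmetry(matrix(runif(6), 2), symmetry_ops("P21/c"),
                         cell(9, 11, 13, beta = 102))
  h0l <- as.matrix(expand.grid(h = -3:3, k = 0, l = -3:3))
  h0l <- h0l[rowSums(h0l != 0) > 0, ]
  chkc <- check_systematic_absences(reflection_list(stc, hkl = h0l), "P21/c")
  expect_true(chkc$consistent)
  expect_error(check_systematic_absences(data.frame(h = integer(0),
                                                    k = integer(0),
                                                    l = integer(0),
                                                    F2 = numeric(0)),
                                         "P212121"),
               "empty")
})

test_that("powder peaks sit at Bragg angles", {
  cl <- cell(4, 4, 4)
  st <- crystal_structure(cl, data.frame(element = "C", x = 0, y = 0, z = 0))
  pp <- powder_pattern(st, wavelength = 1.0, two_theta_range = c(10, 40),
                       step = 0.005, fwhm = 0.05, lorentz = FALSE)
  # expected positions for (100), (110), (111), (200)
  d <- 4 / sqrt(c(1, 2, 3, 4))
  tt <- 2 * asin(1.0 / (2 * d)) * 180 / pi
  for (t0 in tt) {
    win <- abs(pp$two_theta - t0) < 0.3
    i_max <- which.max(pp$intensity[win])
    expect_lt(abs(pp$two_theta[win][i_max] - t0), 0.01)
  }
  # between peaks the pattern returns to (near) zero
  mid <- abs(pp$two_theta - mean(tt[1:2])) < 0.2
  expect_lt(max(pp$intensity[mid]), 0.01 * max(pp$intensity))
})

test_that("powder synthesis validates its grid and wavelength inputs", {
  cl <- cell(4, 4, 4)
  st <- crystal_structure(cl, data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_error(powder_pattern(st, two_theta_range = c(-5, 20)), "range")
  expect_error(powder_pattern(st, step = 0), "step")
  # wavelength too long for the window: nothing diffracts
  expect_error(powder_pattern(st, wavelength = 12, two_theta_range = c(2, 10)),
               "empty")
})
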