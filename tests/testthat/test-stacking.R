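test_that("the vector family obeys the sign table and mirror relations", {
  fam <- make_vector_family(0.377, 0.250, 0.041)
  v <- fam$vectors
  expect_equal(unname(v["A", ]), c(0.377, 0.250, 0.041))
  expect_equal(unname(v["C", ]), c(-0.377, 0.250, -0.041))
  expect_equal(v["C", c("u", "w")], -v["A", c("u", "w")])
  expect_equal(v["D", c("u", "w")], -v["B", c("u", "w")])
  expect_equal(v["B", "u"], -v["A", "u"])         # mirror flips a
  expect_equal(unname(colSums(v))[c(1, 3)], c(0, 0))  # in-plane parts cancel
  expect_true(all(v[, "v"] == 0.250))
  # identical magnitudes under an orthorhombic metric
  g <- metric_tensor(form_ii_cell())
  mags <- sqrt(rowSums((v %*% g) * v))
  expect_lt(diff(range(mags)) / mags[1], 1e-12)
  # degenerate in-plane parts collapse the family
  deg <- make_vector_family(0, 0.5, 0)$vectors
  expect_true(all(apply(deg, 1, function(r) all(r == c(0, 0.5, 0)))))
  expect_error(make_vector_family(0.3, 0, 0.1), "stacking advance")
})

test_that("periodic sequences repeat the pattern cyclically", {
  expect_equal(periodic_sequence("ABCD", 8)$labels,
               c("A", "B", "C", "D", "A", "B", "C", "D"))
  expect_equal(periodic_sequence("AB", 5)$labels,
               c("A", "B", "A", "B", "A"))
  expect_equal(periodic_sequence("A", 1)$labels, "A")
  expect_error(periodic_sequence("ABQ", 4), "unknown")
})

test_that("fault insertion has the declared statistics and provenance", {
  expect_equal(faulted_sequence("ABCD", 50, 0, seed = 1)$labels,
               periodic_sequence("ABCD", 50)$labels)
  # p = 1 forces a different label at every usable interface
  s1 <- faulted_sequence("ABCD", 1000, 1, seed = 2)
  base <- periodic_sequence("ABCD", 1000)$labels
  expect_true(all(s1$labels[1:999] != base[1:999]))
  expect_setequal(s1$fault_positions, 0:998)
  # binomial sampling check at p = 0.1
  s <- faulted_sequence("ABCD", 10000, 0.1, seed = 3)
  frac <- length(s$fault_positions) / 9999
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 9999))
  expect_true(all(s$fault_positions >= 0 & s$fault_positions <= 9998))
  # determinism
  expect_identical(faulted_sequence("AB", 100, 0.3, seed = 9)$labels,
                   faulted_sequence("AB", 100, 0.3, seed = 9)$labels)
})

test_that("build_stack conserves atoms, layers and closure", {
  motif <- tiny_motif()
  fam <- default_family()
  n_at <- nrow(motif_atoms(motif))
  for (n in c(1, 4, 20)) {
    st <- build_stack(motif, periodic_sequence("ABCD", n), fam)
    expect_equal(nrow(st$atoms), n * n_at)
    expect_equal(n_layers(st), n)
    expect_equal(st$cell$b, n * motif$layer_spacing)
  }
  # single layer reproduces the motif at stacking coordinate 0
  st1 <- build_stack(motif, periodic_sequence("A", 1), fam)
  at <- motif_atoms(motif)
  expect_equal(st1$atoms$x, at$fx - floor(at$fx), tolerance = 1e-12)
  expect_equal(st1$atoms$z, at$fz - floor(at$fz), tolerance = 1e-12)
  expect_true(all(st1$atoms$y == 0))
  # ABCD closes in-plane after 4 layers: layer 4 sits above layer 0
  st5 <- build_stack(motif, periodic_sequence("ABCD", 5), fam)
  ctr <- molecule_centroids(st5)
  l0 <- ctr[ctr$layer == 0, ]; l4 <- ctr[ctr$layer == 4, ]
  dx <- l4$x - l0$x; dz <- l4$z - l0$z
  expect_lt(max(abs(dx - round(dx))), 1e-9)
  expect_lt(max(abs(dz - round(dz))), 1e-9)
})

test_that("period detection matches the printed polytypes and the brute-force oracle", {
  fam <- default_family()
  expect_equal(detect_period(periodic_sequence("ABCD", 12)$labels, fam), 4)
  # Form I-like AB stacking never closes in this frame
  expect_true(is.na(detect_period(periodic_sequence("AB", 100)$labels, fam)))
  # in-plane closure after 2 but full 3D closure only after 4
  fam2 <- make_vector_family(0.5, 0.25, 0)
  expect_equal(detect_period(rep("A", 10), fam2), 4)
  # agreement with the enumeration oracle on random faulted sequences
  for (seed in 1:20) {
    s <- faulted_sequence("ABCD", 60, 0.3, seed = seed)
    famr <- make_vector_family(sample(c(0.25, 0.377, 0.5), 1), 0.25,
                               sample(c(0, 0.041, 0.5), 1))
    expect_identical(detect_period(s$labels, famr),
                     oracle_period(s$labels, famr))
  }
})

test_that("interlayer vectors are recovered exactly and classified back", {
  motif <- form_ii_motif()
  fam <- default_family()
  st <- build_stack(motif, periodic_sequence("ABCD", 8), fam)
  v <- extract_interlayer_vectors(st)
  expect_equal(nrow(v), 7)
  want <- fam$vectors[periodic_sequence("ABCD", 7)$labels, ]
  expect_equal(unname(v), unname(want), tolerance = 1e-9)
  expect_equal(unname(v[, "v"]), rep(0.250, 7), tolerance = 1e-9)
  expect_equal(classify_sequence(v, fam), "ABCDABC")
})

test_that("minimal-magnitude reduction picks the short representative", {
  motif <- tiny_motif()
  fam_long <- make_vector_family(0.9, 0.25, 0)
  st <- build_stack(motif, periodic_sequence("A", 3), fam_long)
  v <- extract_interlayer_vectors(st)
  expect_equal(unname(v[1, ]), c(-0.1, 0.25, 0), tolerance = 1e-9)
})

test_that("vectors away from the family are labelled X", {
  fam <- default_family()
  v <- rbind(fam$vectors["A", ], c(0.2, 0.25, 0.2))
  expect_equal(classify_sequence(v, fam, tol = 0.02), "AX")
})

test_that("extraction errors on non-rigid or too-small stacks", {
  motif <- tiny_motif()
  fam <- default_family()
  st1 <- build_stack(motif, periodic_sequence("A", 1), fam)
  expect_error(extract_interlayer_vectors(st1), "at least 2 layers")
  st <- build_stack(motif, periodic_sequence("ABCD", 4), fam)
  jig <- st
  sel <- jig$atoms$layer == 2 & jig$atoms$mol == min(jig$atoms$mol[jig$atoms$layer == 2])
  jig$atoms$x[sel] <- jig$atoms$x[sel] + 0.08    # push one molecule off-lattice
  expect_error(extract_interlayer_vectors(jig), "rigidity")
})

test_that("the classify/extract round trip survives faulting (property)", {
  motif <- tiny_motif()
  fam <- default_family()
  for (seed in 1:12) {
    p <- c(0, 0.1, 0.3, 0.6, 1)[(seed %% 5) + 1]
    n <- c(5, 17, 40, 200)[(seed %% 4) + 1]
    s <- faulted_sequence("ABCD", n, p, seed = seed)
    st <- build_stack(motif, s, fam)
    got <- classify_sequence(extract_interlayer_vectors(st), fam)
    expect_equal(got, paste(s$labels[seq_len(n - 1)], collapse = ""),
                 info = sprintf("seed %d, p %.1f, n %d", seed, p, n))
  }
})
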