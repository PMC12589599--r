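# shared fixtures, all generated in code

hex_mol <- function() make_toy_molecule(6, 1.4, seed = 0)

tiny_motif <- function(seed = 1, n_mol = 2)
  make_layer_motif(hex_mol(), n_mol, footprint = c(10, 14, 90),
                   layer_spacing = 3.2, seed = seed)

default_family <- function() make_vector_family()

# brute-force period oracle: enumerate cumulative sums directly
oracle_period <- function(labels, family, tol = 1e-9) {
  cum <- c(0, 0, 0)
  for (n in seq_along(labels)) {
    cum <- cum + family$vectors[labels[n], ]
    if (all(abs(cum - round(cum)) <= tol)) return(n)
  }
  NA_integer_
}

# axial reflection set up to a maximum index
axial_hkl <- function(hmax = 8) {
  rbind(cbind(1:hmax, 0, 0), cbind(0, 1:hmax, 0), cbind(0, 0, 1:hmax))
}
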