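#' Read a two- or three-column powder pattern
#'
#' Whitespace-separated xy (2-theta, intensity) or xye (2-theta,
#' intensity, sigma) text; lines starting with `#` are comments.  A
#' header comment of the form `# wavelength <value>` sets the
#' wavelength; otherwise the `wavelength` argument applies.  Three
#' column files populate weights as 1/sigma^2.
#'
#' @param path File path.
#' @param wavelength Fallback wavelength in angstrom.
#' @return A `"powder_pattern"`.
#' @export
read_xy <- function(path, wavelength = 0.82408) {
  lines <- readLines(path, warn = FALSE)
  lam <- wavelength
  hdr <- grep("^#\\s*wavelength", lines, value = TRUE)
  if (length(hdr))
    lam <- as.numeric(sub("^#\\s*wavelength\\s+", "", hdr[1]))
  dat <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(dat)) stop("format error: no data rows in ", path)
  m <- do.call(rbind, lapply(strsplit(trimws(dat), "\\s+"), as.numeric))
  if (ncol(m) < 2) stop("format error: expected 2 or 3 columns")
  if (any(diff(m[, 1]) <= 0))
    stop("format error: 2-theta grid must be strictly increasing")
  sigma <- if (ncol(m) >= 3) m[, 3] else NULL
  powder_pattern_object(m[, 1], m[, 2], lam,
                        weights = if (!is.null(sigma)) 1 / sigma^2,
                        sigma = sigma)
}

#' Write a powder pattern as xy/xye text
#'
#' @param pattern A `"powder_pattern"`.
#' @param path Output path.
#' @param seed Optional integer recorded in the header for provenance.
#' @return Invisibly, the path.
#' @export
write_xy <- function(pattern, path, seed = NULL) {
  hdr <- c(sprintf("# wavelength %.6f", pattern$wavelength),
           if (!is.null(seed)) sprintf("# seed %d", as.integer(seed)))
  body <- if (!is.null(pattern$sigma))
    sprintf("%.6f %.6f %.6f", pattern$two_theta, pattern$intensity,
            pattern$sigma)
  else sprintf("%.6f %.6f", pattern$two_theta, pattern$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a structure as a P1 CIF
#'
#' Minimal core CIF: cell, "P 1" symmetry, fractional atom sites, and
#' provenance comments (seed and stacking sequence when the structure
#' carries them).
#'
#' @param structure A `"crystal_structure"`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cif <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  at <- structure$atoms
  if (nrow(at) == 0) stop("empty structure")
  cl <- structure$cell
  meta <- structure$meta
  hdr <- c("data_polystack",
           if (!is.null(meta$seed) && !is.na(meta$seed))
             sprintf("# seed %d", as.integer(meta$seed)),
           if (!is.null(meta$sequence))
             sprintf("# stacking_sequence %s", meta$sequence),
           sprintf("_cell_length_a %.6f", cl$a),
           sprintf("_cell_length_b %.6f", cl$b),
           sprintf("_cell_length_c %.6f", cl$c),
           sprintf("_cell_angle_alpha %.6f", cl$alpha),
           sprintf("_cell_angle_beta %.6f", cl$beta),
           sprintf("_cell_angle_gamma %.6f", cl$gamma),
           "_symmetry_space_group_name_H-M 'P 1'",
           "loop_",
           "_atom_site_label",
           "_atom_site_type_symbol",
           "_atom_site_fract_x",
           "_atom_site_fract_y",
           "_atom_site_fract_z")
  lab <- sprintf("%s%d", at$element, seq_len(nrow(at)))
  body <- sprintf("%s %s %.6f %.6f %.6f", lab, at$element,
                  at$x, at$y, at$z)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# strip an esd like "10.10(10)" to its central value
#' @noRd
strip_esd <- function(x) as.numeric(sub("\\(.*\\)", "", x))

#' Read a small-molecule CIF
#'
#' Minimal dialect: cell items, the H-M space-group symbol (P 1,
#' P 21/c and P 21 21 21 recognized and expanded; anything else raises
#' an error directing the user to pre-expand to P1) or an explicit
#' `_symmetry_equiv_pos_as_xyz` loop, and fractional atom sites.  esds
#' like `10.10(10)` are stripped to the central value.
#'
#' @param path File path.
#' @return A `"crystal_structure"` expanded to P1.
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(lines)

  grab <- function(tag) {
    i <- grep(paste0("^", tag, "\\b"), stripped)
    if (!length(i))
      stop(sprintf("parse error: missing %s in %s", tag, path))
    strip_esd(strsplit(stripped[i[1]], "\\s+")[[1]][2])
  }
  cl <- cell(grab("_cell_length_a"), grab("_cell_length_b"),
             grab("_cell_length_c"),
             tryCatch(grab("_cell_angle_alpha"), error = function(e) 90),
             tryCatch(grab("_cell_angle_beta"), error = function(e) 90),
             tryCatch(grab("_cell_angle_gamma"), error = function(e) 90))

  # symmetry: explicit xyz loop wins, else the H-M symbol
  ops <- NULL
  ix <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
             stripped)
  if (length(ix)) {
    j <- ix[1] + 1
    xyz <- character(0)
    while (j <= length(stripped) && !grepl("^(_|loop_|data_)", stripped[j]) &&
           nzchar(stripped[j])) {
      xyz <- c(xyz, gsub("['\"]", "", stripped[j]))
      j <- j + 1
    }
    ops <- lapply(xyz, parse_symop_xyz)
  } else {
    i <- grep("^_symmetry_space_group_name_H-M|^_space_group_name_H-M", stripped)
    sym <- if (length(i))
      toupper(gsub("[' \"]", "", sub("^\\S+\\s+", "", stripped[i[1]])))
    else "P1"
    ops <- switch(sym,
      "P1" = symmetry_ops("P1"),
      "P21/C" = symmetry_ops("P21/c"),
      "P212121" = symmetry_ops("P212121"),
      stop(sprintf("parse error (line %d): unsupported space group '%s'; pre-expand the model to P1",
                   if (length(i)) i[1] else NA_integer_, sym)))
  }

  # atom loop
  li <- grep("^loop_", stripped)
  at <- NULL
  for (start in li) {
    j <- start + 1
    tags <- character(0)
    while (j <= length(stripped) && grepl("^_", stripped[j])) {
      tags <- c(tags, sub("\\s.*", "", stripped[j]))
      j <- j + 1
    }
    if (!"_atom_site_fract_x" %in% tags) next
    rows <- character(0)
    while (j <= length(stripped) && nzchar(stripped[j]) &&
           !grepl("^(_|loop_|data_|#)", stripped[j])) {
      rows <- c(rows, stripped[j]); j <- j + 1
    }
    tab <- do.call(rbind, strsplit(rows, "\\s+"))
    cols <- match(c("_atom_site_type_symbol", "_atom_site_label",
                    "_atom_site_fract_x", "_atom_site_fract_y",
                    "_atom_site_fract_z"), tags)
    el <- if (!is.na(cols[1])) tab[, cols[1]]
          else gsub("[0-9]+$", "", tab[, cols[2]])
    at <- data.frame(element = el,
                     x = strip_esd(tab[, cols[3]]),
                     y = strip_esd(tab[, cols[4]]),
                     z = strip_esd(tab[, cols[5]]),
                     stringsAsFactors = FALSE)
    break
  }
  if (is.null(at))
    stop("parse error: no atom-site loop with fractional coordinates in ",
         path)
  if (length(ops) > 1) {
    expand_symmetry(as.matrix(at[, c("x", "y", "z")]), ops, cl,
                    elements = at$element)
  } else {
    crystal_structure(cl, at)
  }
}

# parse an operator string like '-x+1/2, y, 1/2-z'
#' @noRd
parse_symop_xyz <- function(s) {
  parts <- strsplit(tolower(s), ",")[[1]]
  if (length(parts) != 3) stop("parse error: bad symmetry operator: ", s)
  rmat <- matrix(0, 3, 3); tvec <- numeric(3)
  for (i in 1:3) {
    term <- gsub("\\s", "", parts[i])
    # coordinate terms: the sign is whatever character precedes the letter
    for (j in 1:3) {
      v <- c("x", "y", "z")[j]
      m <- regmatches(term, regexpr(paste0("[+-]?", v), term))
      if (length(m) && nzchar(m))
        rmat[i, j] <- if (startsWith(m, "-")) -1 else 1
    }
    # translation: whatever remains after removing +-x/y/z tokens
    tr <- gsub("[+-]?[xyz]", "", term)
    if (nzchar(tr)) {
      if (grepl("/", tr)) {
        num <- as.numeric(strsplit(gsub("\\+", "", tr), "/")[[1]])
        tvec[i] <- num[1] / num[2]
      } else tvec[i] <- as.numeric(tr)
    }
  }
  list(R = rmat, t = tvec %% 1)
}

#' Read an orientation matrix file
#'
#' Either nine whitespace-separated numbers (row-major UB; supply the
#' cell separately) or JSON with `ub` (row-major, 9 numbers or 3x3) and
#' an embedded `cell` block (a, b, c, alpha, beta, gamma).
#'
#' @param path File path.
#' @param cell Optional `"cell"`, required for the 9-number format.
#' @return An `"orientation_matrix"`.
#' @export
read_orientation_matrix <- function(path, cell = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*\\{", txt)) {
    j <- jsonlite::fromJSON(txt)
    ub <- matrix(as.numeric(unlist(j$ub)), 3, 3, byrow = TRUE)
    if (!is.null(j$cell))
      cell <- do.call("cell", as.list(j$cell)[c("a", "b", "c",
                                                "alpha", "beta", "gamma")])
  } else {
    nums <- as.numeric(strsplit(trimws(gsub("#[^\n]*", "", txt)),
                                "\\s+")[[1]])
    if (length(nums) != 9)
      stop("expected 9 numbers in a plain-text orientation matrix file")
    ub <- matrix(nums, 3, 3, byrow = TRUE)
  }
  if (is.null(cell)) stop("no cell supplied or embedded for ", path)
  orientation_matrix(cell, ub = ub)
}

#' Write an orientation matrix as JSON with embedded cell
#'
#' @param om An `"orientation_matrix"`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_orientation_matrix <- function(om, path) {
  jsonlite::write_json(list(ub = unname(as.data.frame(t(om$ub))),
                            cell = om$cell[c("a", "b", "c", "alpha",
                                             "beta", "gamma")]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Missing fields fall back to the package defaults: the Form II-like
#' motif and family, an ABCD base pattern, the 0.82408 angstrom
#' synchrotron wavelength, and a fault probability of 0.1.
#'
#' @param path YAML or JSON file path (by extension; `.json` uses
#'   jsonlite).
#' @return Named list with components `seed`, `motif`, `family`,
#'   `sequence`, `diffraction`, `fit`.
#' @export
read_run_config <- function(path) {
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  defaults <- list(
    seed = 1L,
    motif = list(n_ring_atoms = 6, bond_length = 1.4, n_mol = 4,
                 footprint = c(10.10, 17.91, 90),
                 layer_spacing = 12.54 / 4),
    family = list(u = 0.377, v = 0.250, w = 0.041),
    sequence = list(pattern = "ABCD", n_layers = 20, p_fault = 0.1),
    diffraction = list(wavelength = 0.82408,
                       two_theta_range = c(2, 30), step = 0.01,
                       fwhm = 0.05, eta = 0.5),
    fit = list(bg_degree = 3))
  merge_lists(defaults, user)
}

#' @noRd
merge_lists <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_lists(base[[nm]], override[[nm]])
    else override[[nm]]
  }
  base
}
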