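# Synthetic RNA decoy ensembles with known ground-truth quality: an ideal
# A-form duplex reference, Gaussian coordinate perturbation, targeted
# glycosidic base flips that break pairing geometry while leaving the
# backbone intact, and a fixture writer (plain-text PDB).

# Idealized base-atom coordinates (Angstrom) in the standard base-pair
# reference frame (z = 0 base plane, Watson-Crick edge toward -y); the
# complementary base of a pair is this frame rotated 180 degrees about x.
BASE_FRAMES <- list(
  A = rbind("C1'" = c(-2.479, 5.346, 0.000),
            N9 = c(-1.291, 4.498, 0.000), C8 = c(0.024, 4.897, 0.000),
            N7 = c(0.877, 3.902, 0.000), C5 = c(0.071, 2.771, 0.000),
            C6 = c(0.369, 1.398, 0.000), N6 = c(1.611, 0.909, 0.000),
            N1 = c(-0.668, 0.532, 0.000), C2 = c(-1.912, 1.023, 0.000),
            N3 = c(-2.320, 2.290, 0.000), C4 = c(-1.267, 3.124, 0.000)),
  G = rbind("C1'" = c(-2.477, 5.399, 0.000),
            N9 = c(-1.289, 4.551, 0.000), C8 = c(0.023, 4.962, 0.000),
            N7 = c(0.870, 3.969, 0.000), C5 = c(0.071, 2.833, 0.000),
            C6 = c(0.424, 1.460, 0.000), O6 = c(1.554, 0.955, 0.000),
            N1 = c(-0.700, 0.641, 0.000), C2 = c(-1.999, 1.087, 0.000),
            N2 = c(-2.949, 0.139, -0.001), N3 = c(-2.342, 2.364, 0.001),
            C4 = c(-1.265, 3.177, 0.000)),
  C = rbind("C1'" = c(-2.477, 5.402, 0.000),
            N1 = c(-1.285, 4.542, 0.000), C2 = c(-1.472, 3.158, 0.000),
            O2 = c(-2.628, 2.709, 0.001), N3 = c(-0.391, 2.344, 0.000),
            C4 = c(0.837, 2.868, 0.000), N4 = c(1.875, 2.027, 0.001),
            C5 = c(1.056, 4.275, 0.000), C6 = c(-0.023, 5.068, 0.000)),
  U = rbind("C1'" = c(-2.481, 5.354, 0.000),
            N1 = c(-1.284, 4.500, 0.000), C2 = c(-1.462, 3.131, 0.000),
            O2 = c(-2.563, 2.608, 0.000), N3 = c(-0.302, 2.397, 0.000),
            C4 = c(0.989, 2.884, 0.000), O4 = c(1.935, 2.094, -0.001),
            C5 = c(1.089, 4.311, 0.000), C6 = c(-0.024, 5.053, 0.000))
)

# Simplified sugar/phosphate trace: offsets from C1' in the base frame.
C4P_OFFSET <- c(-1.0, 0.8, 1.85)
P_OFFSET <- c(-1.4, 1.3, 3.3)

# A-form helix parameters (standard fiber values).
AFORM_RISE <- 2.81     # Angstrom per base pair
AFORM_TWIST <- 32.7    # degrees per base pair
AFORM_XDISP <- -4.4    # base-pair displacement from the helix axis (Angstrom)
# Inclination at the low end of the A-family range: keeps inter-pair
# (stacking-diagonal) donor-acceptor distances >6 Angstrom, so only the
# designed pairs fall anywhere near hydrogen-bonding geometry.
AFORM_INCL <- 10       # base-pair inclination (degrees)

COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

base_frame_atoms <- function(base) {
  fr <- BASE_FRAMES[[base]]
  c1 <- fr["C1'", ]
  rbind(fr, "C4'" = c1 + C4P_OFFSET, P = c1 + P_OFFSET)
}

make_residue_structure <- function(id, bases, chains, resnos, atom_list) {
  structure(list(
    id = id, bases = bases, sequence = paste(bases, collapse = ""),
    chain = chains, resno = resnos, insert = rep("", length(bases)),
    atoms = atom_list,
    incomplete = !vapply(atom_list, function(a) "C1'" %in% rownames(a),
                         logical(1)),
    length = length(bases)
  ), class = "rna_structure")
}

#' Ideal A-form RNA duplex
#'
#' Builds a double helix from idealized base-pair geometry: each Watson-Crick
#' pair is placed in the standard base-pair reference frame (complementary
#' base rotated 180 degrees about x) and pair k is rotated by
#' `(k-1) * 32.7` degrees and raised by `(k-1) * 2.81` Angstrom along the
#' helix axis. Chains A (5'->3' along the axis) and B (complementary,
#' antiparallel) carry all atoms needed by the geometric annotator, plus a
#' simplified C4'/P backbone trace.
#'
#' @param n_bp Number of base pairs (>= 2).
#' @param sequence Optional strand-A sequence (length `n_bp`, letters ACGU);
#'   the default alternates `A, U`. In a regular helix the minor-groove
#'   edges of stacking-diagonal neighbours approach each other; with G
#'   present, its N2 donor can come within hydrogen-bond range of a
#'   diagonal purine acceptor, leaving spurious near-contacts right at the
#'   annotator's thresholds. A/U duplexes have no minor-groove donors, so
#'   designed pairs are the only interactions anywhere near hydrogen-bond
#'   geometry and the annotator's closed loop is robust under perturbation.
#' @param id Structure identifier.
#' @return List with `structure` (an `rna_structure` of `2 * n_bp` residues)
#'   and `pairs` (the designed pair list: residue indices after chain
#'   concatenation, pair k is `(k, 2*n_bp + 1 - k)`, all `canonical_wc`).
#' @export
ideal_duplex <- function(n_bp, sequence = NULL, id = "ideal_duplex") {
  stopifnot(n_bp >= 2)
  seq_a <- if (is.null(sequence)) {
    rep_len(c("A", "U"), n_bp)
  } else {
    s <- strsplit(toupper(sequence), "")[[1]]
    stopifnot(length(s) == n_bp, all(s %in% names(COMPLEMENT)))
    s
  }
  seq_b_by_pair <- COMPLEMENT[seq_a]   # base paired with strand-A residue k
  flip <- diag(c(1, -1, -1))
  incl <- AFORM_INCL * pi / 180
  Rx <- matrix(c(1, 0, 0,
                 0, cos(incl), -sin(incl),
                 0, sin(incl), cos(incl)), nrow = 3, byrow = TRUE)
  place <- function(coords, k) {
    # pair as a unit: incline about its x-axis, displace off the helix
    # axis, then twist and rise along z
    out <- coords %*% t(Rx)
    out[, 1] <- out[, 1] + AFORM_XDISP
    theta <- (k - 1) * AFORM_TWIST * pi / 180
    Rz <- matrix(c(cos(theta), -sin(theta), 0,
                   sin(theta), cos(theta), 0,
                   0, 0, 1), nrow = 3, byrow = TRUE)
    out <- out %*% t(Rz)
    out[, 3] <- out[, 3] + (k - 1) * AFORM_RISE
    out
  }
  atoms_a <- lapply(seq_len(n_bp), function(k) {
    place(base_frame_atoms(seq_a[k]), k)
  })
  # chain B residue m sits at helical frame k = n_bp + 1 - m (antiparallel)
  atoms_b <- lapply(seq_len(n_bp), function(m) {
    k <- n_bp + 1 - m
    place(base_frame_atoms(seq_b_by_pair[k]) %*% t(flip), k)
  })
  s <- make_residue_structure(
    id,
    bases = c(seq_a, unname(seq_b_by_pair[n_bp:1])),
    chains = rep(c("A", "B"), each = n_bp),
    resnos = c(seq_len(n_bp), seq_len(n_bp)),
    atom_list = c(atoms_a, atoms_b)
  )
  pairs <- data.frame(
    i = seq_len(n_bp),
    j = 2 * n_bp + 1 - seq_len(n_bp),
    category = ifelse(paste0(seq_a, seq_b_by_pair) %in% c("GU", "UG"),
                      "wobble", "canonical_wc"),
    detail = paste0(seq_a, "-", seq_b_by_pair),
    stringsAsFactors = FALSE
  )
  list(structure = s, pairs = pairs)
}

#' Fully extended single strand
#'
#' Residues laid out along a straight line, far beyond pairing distance:
#' yields an empty base-pair map by construction.
#'
#' @param n Residue count.
#' @param spacing Inter-residue spacing (Angstrom).
#' @param id Structure identifier.
#' @return An `rna_structure`.
#' @export
extended_strand <- function(n, spacing = 6.5, id = "extended_strand") {
  stopifnot(n >= 1)
  bases <- rep_len(c("A", "C", "G", "U"), n)
  atoms <- lapply(seq_len(n), function(k) {
    a <- base_frame_atoms(bases[k])
    a[, 1] <- a[, 1] + (k - 1) * spacing
    a
  })
  make_residue_structure(id, bases, rep("A", n), seq_len(n), atoms)
}

#' Perturb a structure with Gaussian noise plus a random rigid motion
#'
#' Adds i.i.d. zero-mean Gaussian noise (standard deviation `sigma`, per
#' coordinate) to every atom and then applies a random rotation and
#' translation. `sigma = 0` leaves the shape rigidly moved but undistorted.
#' Deterministic for a fixed `(sigma, seed)`.
#'
#' @param s An `rna_structure`.
#' @param sigma Noise level in Angstrom (>= 0).
#' @param seed Integer seed.
#' @param id Identifier for the perturbed copy.
#' @return A new `rna_structure`.
#' @export
perturb_structure <- function(s, sigma, seed, id = paste0(s$id, "_perturbed")) {
  stopifnot(sigma >= 0)
  with_seed(seed, {
    R <- random_rotation()
    tr <- stats::runif(3, -15, 15)
    atoms <- lapply(s$atoms, function(a) {
      noisy <- a + matrix(stats::rnorm(length(a), sd = sigma), nrow = nrow(a))
      out <- noisy %*% t(R)
      out <- sweep(out, 2, tr, `+`)
      rownames(out) <- rownames(a)
      out
    })
    out <- s
    out$id <- id
    out$atoms <- atoms
    out
  })
}

#' Break designed base pairs by glycosidic base flips
#'
#' For a random fraction of the designed pairs, one partner's base (all atoms
#' except C1', C4' and P) is rotated about its glycosidic bond axis
#' (C1'->N9 for purines, C1'->N1 for pyrimidines) by a random 90-150 degree
#' angle. This destroys the hydrogen-bonding geometry the annotator detects
#' while leaving the C1' backbone trace -- and hence the TM-score -- intact.
#'
#' @param s An `rna_structure`.
#' @param designed_pairs Data frame with columns `i`, `j` (the pairs to
#'   sample from, e.g. from [ideal_duplex()]).
#' @param fraction Fraction of pairs to disrupt, in [0, 1].
#' @param seed Integer seed.
#' @param id Identifier for the modified copy.
#' @return A new `rna_structure`.
#' @export
disrupt_pairs <- function(s, designed_pairs, fraction, seed,
                          id = paste0(s$id, "_flipped")) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_sel <- round(fraction * nrow(designed_pairs))
  out <- s
  out$id <- id
  if (n_sel == 0) return(out)
  with_seed(seed, {
    sel <- sample(nrow(designed_pairs), n_sel)
    for (row in sel) {
      pair <- designed_pairs[row, ]
      res <- if (stats::runif(1) < 0.5) pair$i else pair$j
      angle <- stats::runif(1, 90, 150) * pi / 180
      out$atoms[[res]] <- flip_base(out$atoms[[res]], out$bases[res], angle)
    }
    out
  })
}

flip_base <- function(a, base, angle) {
  gly <- if (is_purine(base)) "N9" else "N1"
  if (!all(c("C1'", gly) %in% rownames(a))) return(a)
  origin <- a["C1'", ]
  axis <- a[gly, ] - origin
  R <- rotation_about_axis(axis, angle)
  keep <- rownames(a) %in% c("C1'", "C4'", "P")
  moved <- sweep(sweep(a, 2, origin) %*% t(R), 2, origin, `+`)
  a[!keep, ] <- moved[!keep, ]
  a
}

#' Decoy ensemble specification
#'
#' @param n_bp Base pairs of the reference duplex (ensemble length is
#'   `2 * n_bp` nt).
#' @param noise_grid Per-decoy Cartesian perturbation sigma (Angstrom); its
#'   length is the number of decoys. Default: three graded tiers
#'   (0.1, 1.0, 3.0 Angstrom), four decoys each.
#' @param bp_disruption Per-decoy fraction of designed pairs broken by
#'   glycosidic flips (default none).
#' @param seed Integer seed driving all randomness.
#' @return A `decoy_spec`.
#' @export
decoy_spec <- function(n_bp = 15,
                       noise_grid = rep(c(0.1, 1.0, 3.0), each = 4),
                       bp_disruption = rep(0, length(noise_grid)),
                       seed = 1L) {
  stopifnot(n_bp >= 2, length(noise_grid) >= 2, all(noise_grid >= 0),
            length(bp_disruption) == length(noise_grid),
            all(bp_disruption >= 0), all(bp_disruption <= 1))
  structure(list(n_bp = n_bp, n_decoys = length(noise_grid),
                 noise_grid = noise_grid, bp_disruption = bp_disruption,
                 seed = as.integer(seed)),
            class = "decoy_spec")
}

#' Generate a decoy ensemble with known ground truth
#'
#' Builds the ideal duplex reference, derives one decoy per entry of the
#' noise grid (optional glycosidic disruption, then Gaussian perturbation
#' plus a random rigid motion), writes the decoys as PDB files under
#' `dir/decoys/`, the reference to `dir/reference.pdb`, and a ground-truth
#' table to `dir/truth.csv`. Ground-truth quality of a decoy is its TM-score
#' to the unperturbed reference (reference-based quality, computable
#' in-house). Deterministic for a fixed spec.
#'
#' @param spec A [decoy_spec()].
#' @param dir Output directory.
#' @return List with `ensemble` (decoys re-read via [read_ensemble()], so the
#'   round trip through PDB is part of the pipeline), `truth` (data frame
#'   `target_id, decoy_id, tm_ref, sigma, bp_disruption`), `reference`,
#'   `designed_pairs`, `dir`.
#' @export
make_ensemble <- function(spec, dir) {
  stopifnot(inherits(spec, "decoy_spec"))
  ref <- ideal_duplex(spec$n_bp)
  decoy_dir <- file.path(dir, "decoys")
  dir.create(decoy_dir, recursive = TRUE, showWarnings = FALSE)
  L <- ref$structure$length
  params <- tm_params(L)
  ids <- sprintf("decoy_%02d", seq_len(spec$n_decoys))
  tm_ref <- numeric(spec$n_decoys)
  for (k in seq_len(spec$n_decoys)) {
    s <- ref$structure
    if (spec$bp_disruption[k] > 0) {
      s <- disrupt_pairs(s, ref$pairs, spec$bp_disruption[k],
                         seed = spec$seed * 1000L + 2L * k)
    }
    s <- perturb_structure(s, spec$noise_grid[k],
                           seed = spec$seed * 1000L + 2L * k + 1L,
                           id = ids[k])
    tm_ref[k] <- tm_score(s, ref$structure, params)
    write_pdb(s, file.path(decoy_dir, paste0(ids[k], ".pdb")))
  }
  write_pdb(ref$structure, file.path(dir, "reference.pdb"))
  truth <- data.frame(target_id = basename(normalizePath(dir)),
                      decoy_id = ids, tm_ref = tm_ref,
                      sigma = spec$noise_grid,
                      bp_disruption = spec$bp_disruption,
                      stringsAsFactors = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  list(ensemble = read_ensemble(decoy_dir), truth = truth, reference = ref,
       designed_pairs = ref$pairs, dir = dir)
}

#' Write an `rna_structure` as a PDB file
#'
#' Fixture writer: standard fixed-width ATOM records (first model only,
#' occupancy 1.00), 1-based author residue numbering.
#'
#' @param s An `rna_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  lines <- character(0)
  serial <- 0L
  for (k in seq_len(s$length)) {
    a <- s$atoms[[k]]
    for (r in seq_len(nrow(a))) {
      serial <- serial + 1L
      name <- rownames(a)[r]
      name_field <- if (nchar(name) >= 4) substr(name, 1, 4)
        else sprintf(" %-3s", name)
      lines[length(lines) + 1L] <- sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name_field, s$bases[k], s$chain[k], s$resno[k],
        a[r, 1], a[r, 2], a[r, 3], 1.00, 0.00, substr(name, 1, 1))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
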