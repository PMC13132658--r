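# Fixtures are generated in code at test time.

# Random base-pair map over `length` residues.
random_map <- function(length, n_pairs, id = "m") {
  cand <- which(upper.tri(matrix(0, length, length)), arr.ind = TRUE)
  cand <- cand[cand[, 2] - cand[, 1] >= 2, , drop = FALSE]
  sel <- cand[sample(nrow(cand), min(n_pairs, nrow(cand))), , drop = FALSE]
  basepair_map(id, length, data.frame(
    i = sel[, 1], j = sel[, 2],
    category = sample(c("canonical_wc", "wobble", "noncanonical"),
                      nrow(sel), replace = TRUE),
    stringsAsFactors = FALSE))
}

# A perturbed 30-nt decoy pair for TM-score tests.
random_decoy_pair <- function(seed, sigma_a = 1, sigma_b = 2, n_bp = 15) {
  ref <- ideal_duplex(n_bp)$structure
  list(a = perturb_structure(ref, sigma_a, seed = seed),
       b = perturb_structure(ref, sigma_b, seed = seed + 10000L))
}

# Random symmetric similarity values in [0, 1] with unit diagonal.
random_similarity_values <- function(n) {
  x <- matrix(stats::runif(n * n), n, n)
  v <- (x + t(x)) / 2
  diag(v) <- 1
  v
}

# Plain-text fixture writers ------------------------------------------------

# PDB with `n_waters` HOH records appended after the nucleotides.
write_pdb_with_waters <- function(s, path, n_waters) {
  write_pdb(s, path)
  lines <- readLines(path)
  lines <- lines[lines != "END"]
  for (w in seq_len(n_waters)) {
    lines <- c(lines, sprintf(
      "HETATM%5d  O   HOH W%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
      9000 + w, w, 50 + w, 50, 50, 1, 0))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Minimal mmCIF with an atom_site loop in PDBx column order.
write_cif <- function(s, path) {
  hdr <- c("data_fixture", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                    "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
                    "auth_seq_id", "auth_asym_id", "pdbx_PDB_model_num")))
  rows <- character(0)
  serial <- 0L
  for (k in seq_len(s$length)) {
    a <- s$atoms[[k]]
    for (r in seq_len(nrow(a))) {
      serial <- serial + 1L
      name <- rownames(a)[r]
      rows <- c(rows, sprintf(
        "ATOM %d %s \"%s\" . %s %s %d ? %.3f %.3f %.3f 1.00 0.00 %d %s 1",
        serial, substr(name, 1, 1), name, s$bases[k], s$chain[k], s$resno[k],
        a[r, 1], a[r, 2], a[r, 3], s$resno[k], s$chain[k]))
    }
  }
  writeLines(c(hdr, rows, "#"), path)
  path
}

# Apply a fixed rigid transform to every atom of a structure.
rigid_move <- function(s, R, tr) {
  s$atoms <- lapply(s$atoms, function(a) {
    out <- sweep(a %*% t(R), 2, tr, `+`)
    rownames(out) <- rownames(a)
    out
  })
  s
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         nrow = 3, byrow = TRUE)
}

# The constructed "all representative atoms exactly d0 apart" pair: two
# stacked rings of points; b displaces every point radially by d0, and the
# optimal superposition is the identity by symmetry.
d0_ring_pair <- function(n = 30, radius = 30, height = 10, d0 = 1) {
  stopifnot(n %% 2 == 0)
  ang <- seq(0, 2 * pi, length.out = n / 2 + 1)[-(n / 2 + 1)]
  ring <- function(r, z) cbind(r * cos(ang), r * sin(ang), z)
  A <- rbind(ring(radius, 0), ring(radius, height))
  B <- rbind(ring(radius + d0, 0), ring(radius + d0, height))
  make_point_structure <- function(xyz, id) {
    atoms <- lapply(seq_len(nrow(xyz)), function(k) {
      m <- matrix(xyz[k, ], nrow = 1, dimnames = list("C1'", c("x", "y", "z")))
      m
    })
    structure(list(id = id, bases = rep("A", nrow(xyz)),
                   sequence = paste(rep("A", nrow(xyz)), collapse = ""),
                   chain = rep("A", nrow(xyz)), resno = seq_len(nrow(xyz)),
                   insert = rep("", nrow(xyz)), atoms = atoms,
                   incomplete = rep(FALSE, nrow(xyz)), length = nrow(xyz)),
              class = "rna_structure")
  }
  list(a = make_point_structure(A, "ring_a"),
       b = make_point_structure(B, "ring_b"), d0 = d0)
}
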