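# Parsing of RNA 3D coordinate files into a uniform residue-level
# representation, and ensemble-level consistency validation.

# Residue names accepted as RNA nucleotides, mapped to their parent base.
# Modified nucleotides with an identifiable standard parent are remapped;
# anything else (ions, waters, amino acids, DNA) is dropped.
RNA_RESIDUE_MAP <- c(
  A = "A", C = "C", G = "G", U = "U",
  RA = "A", RC = "C", RG = "G", RU = "U",
  ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U",
  # common modified nucleotides
  PSU = "U", H2U = "U", "5MU" = "U", "4SU" = "U", OMU = "U", UR3 = "U",
  "1MA" = "A", MIA = "A", MA6 = "A", OMA = "A", I = "A",
  "1MG" = "G", "2MG" = "G", M2G = "G", "7MG" = "G", OMG = "G", YYG = "G",
  QUO = "G", GTP = "G", GDP = "G", G7M = "G",
  "5MC" = "C", OMC = "C", "4OC" = "C",
  ATP = "A", AMP = "A", A23 = "A"
)

# Base ring atoms used for plane fitting and sequence-dependent edge atoms.
PURINE_RING <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

is_purine <- function(base) base %in% c("A", "G")

ring_atoms <- function(base) if (is_purine(base)) PURINE_RING else PYRIMIDINE_RING

#' Read one RNA 3D structure
#'
#' Parses a coordinate file (PDB or mmCIF) into an `rna_structure`: an ordered
#' list of nucleotide residues with named atom coordinates. Only the first
#' model of a multi-model file is used; non-nucleotide residues (waters, ions,
#' proteins, DNA) are dropped; modified nucleotides with an identifiable
#' parent are remapped to it, others are dropped with a warning. Alternate
#' locations keep the highest-occupancy copy (ties: first encountered).
#'
#' @param path Path to the coordinate file.
#' @param format One of `"auto"` (by extension), `"pdb"`, `"cif"`.
#' @param id Decoy identifier; defaults to the file name without extension.
#' @return An object of class `rna_structure` with elements `id`, `sequence`
#'   (one-letter string), `bases` (character vector), `chain`, `resno`,
#'   `insert`, `atoms` (per-residue named coordinate matrices, Angstrom),
#'   `incomplete` (logical, `TRUE` when the residue lacks a C1' atom) and
#'   `length`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_user("cannot read structure file (no such file): ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  tab <- tryCatch(
    if (format == "pdb") parse_pdb_atoms(path) else parse_cif_atoms(path),
    error = function(e) {
      stop_user("failed to parse structure file ", path, ": ", conditionMessage(e))
    }
  )
  id <- id %||% tools::file_path_sans_ext(basename(path))
  build_structure(tab, id = id, path = path)
}

parse_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         rm.insert = FALSE, verbose = FALSE)
  at <- pdb$atom
  data.frame(
    elety = gsub("\\*", "'", trimws(at$elety)),
    alt = ifelse(is.na(at$alt), "", at$alt),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
}

# Minimal mmCIF atom_site loop reader. Honors the column header, keeps the
# first model, tolerates quoted atom names such as "C1'".
parse_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0) stop("no _atom_site loop found")
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1
  tok_re <- "('[^']*'|\"[^\"]*\"|\\S+)"
  rows <- list()
  for (k in body_start:length(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        ln == "loop_" || startsWith(ln, "data_")) break
    toks <- regmatches(ln, gregexpr(tok_re, ln))[[1]]
    toks <- gsub("^['\"]|['\"]$", "", toks)
    if (length(toks) != length(cols)) {
      stop("atom_site row ", k, " has ", length(toks),
           " fields, expected ", length(cols))
    }
    rows[[length(rows) + 1L]] <- toks
  }
  if (length(rows) == 0) stop("empty _atom_site loop")
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  get_col <- function(...) {
    for (nm in c(...)) if (nm %in% cols) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  clean <- function(v) ifelse(v %in% c(".", "?") | is.na(v), "", v)
  model <- get_col("pdbx_PDB_model_num")
  keep <- if (all(is.na(model))) rep(TRUE, nrow(m)) else model == model[1]
  df <- data.frame(
    elety = gsub("\\*", "'", clean(get_col("label_atom_id", "auth_atom_id"))),
    alt = clean(get_col("label_alt_id")),
    resid = clean(get_col("auth_comp_id", "label_comp_id")),
    chain = clean(get_col("auth_asym_id", "label_asym_id")),
    resno = suppressWarnings(as.integer(get_col("auth_seq_id", "label_seq_id"))),
    insert = clean(get_col("pdbx_PDB_ins_code")),
    x = as.numeric(get_col("Cartn_x")),
    y = as.numeric(get_col("Cartn_y")),
    z = as.numeric(get_col("Cartn_z")),
    o = suppressWarnings(as.numeric(clean(get_col("occupancy")))),
    stringsAsFactors = FALSE
  )
  df$o[is.na(df$o)] <- 1
  df[keep, , drop = FALSE]
}

build_structure <- function(tab, id, path) {
  tab <- tab[tab$resid %in% names(RNA_RESIDUE_MAP), , drop = FALSE]
  if (nrow(tab) == 0) {
    stop_user("empty structure: no RNA nucleotide residues in ", path)
  }
  tab$base <- unname(RNA_RESIDUE_MAP[tab$resid])
  # altloc: highest occupancy per (chain, resno, insert, atom); stable ties
  key <- paste(tab$chain, tab$resno, tab$insert, tab$elety, sep = "\r")
  ord <- order(key, -tab$o, seq_len(nrow(tab)), method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(paste(tab$chain, tab$resno, tab$insert, tab$elety,
                               sep = "\r")), , drop = FALSE]
  # residue order: chain, residue number, insertion code
  rkey <- paste(tab$chain, tab$resno, tab$insert, sep = "\r")
  rord <- order(tab$chain, tab$resno, tab$insert, method = "radix")
  tab <- tab[rord, , drop = FALSE]
  rkey <- rkey[rord]
  if (any(!is.finite(tab$x) | !is.finite(tab$y) | !is.finite(tab$z))) {
    stop_user("non-finite coordinates in ", path)
  }
  split_idx <- split(seq_len(nrow(tab)), factor(rkey, levels = unique(rkey)))
  atoms <- lapply(split_idx, function(ii) {
    mat <- as.matrix(tab[ii, c("x", "y", "z")])
    rownames(mat) <- tab$elety[ii]
    dimnames(mat)[[2]] <- c("x", "y", "z")
    mat
  })
  first <- vapply(split_idx, `[`, integer(1), 1L)
  s <- structure(list(
    id = id,
    bases = tab$base[first],
    sequence = paste(tab$base[first], collapse = ""),
    chain = tab$chain[first],
    resno = tab$resno[first],
    insert = tab$insert[first],
    atoms = unname(atoms),
    incomplete = !vapply(atoms, function(a) "C1'" %in% rownames(a), logical(1)),
    length = length(atoms)
  ), class = "rna_structure")
  if (all(s$incomplete)) {
    stop_user("empty structure: no residue with a C1' atom in ", path)
  }
  s
}

#' Per-residue representative-atom coordinates
#'
#' Returns the L x 3 matrix of trace coordinates used by the TM-score
#' superposition: for each residue the first atom present among `priority`
#' (default C1', then C4', then P); rows are `NA` when none is present.
#'
#' @param s An `rna_structure`.
#' @param priority Atom-name fallback order.
#' @return Numeric L x 3 matrix.
#' @export
rep_coords <- function(s, priority = c("C1'", "C4'", "P")) {
  out <- matrix(NA_real_, nrow = s$length, ncol = 3)
  for (k in seq_len(s$length)) {
    a <- s$atoms[[k]]
    hit <- priority[priority %in% rownames(a)]
    if (length(hit) > 0) out[k, ] <- a[hit[1], ]
  }
  out
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %s: %d nt, %d chain(s)\n",
              x$id, x$length, length(unique(x$chain))))
  cat("  sequence: ",
      if (nchar(x$sequence) > 60) paste0(substr(x$sequence, 1, 57), "...")
      else x$sequence, "\n", sep = "")
  invisible(x)
}

#' Read a directory of decoys as one ensemble
#'
#' Reads every structure file in `dir` (lexicographic filename order, so the
#' ensemble is independent of filesystem listing order), validates that all
#' members model the same sequence, and excludes inconsistent members with a
#' warning. The consensus sequence is the one shared by the largest subset of
#' decoys (ties broken toward the subset containing the lexicographically
#' smallest id).
#'
#' @param dir Directory containing `.pdb` / `.cif` files.
#' @param pattern Filename regexp selecting structure files.
#' @return An `rna_ensemble`: list with `target_id`, `structures` (list of
#'   `rna_structure`), `common_length`, `n`, `excluded` (ids dropped).
#' @export
read_ensemble <- function(dir, pattern = "\\.(pdb|ent|cif|mmcif)$") {
  if (!dir.exists(dir)) stop_user("no such ensemble directory: ", dir)
  files <- list.files(dir, pattern = pattern, full.names = TRUE,
                      ignore.case = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (length(files) < 2) {
    stop_user("ensemble too small: need at least 2 structure files in ", dir)
  }
  structures <- list()
  for (f in files) {
    s <- tryCatch(read_structure(f), error = function(e) {
      warning("skipping unparseable decoy ", basename(f), ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(s)) structures[[length(structures) + 1L]] <- s
  }
  if (length(structures) < 2) {
    stop_user("ensemble too small: fewer than 2 parseable structures in ", dir)
  }
  seqs <- vapply(structures, `[[`, character(1), "sequence")
  ids <- vapply(structures, `[[`, character(1), "id")
  groups <- split(seq_along(seqs), seqs)
  sizes <- lengths(groups)
  first_id <- vapply(groups, function(ii) min(ids[ii]), character(1))
  best <- order(-sizes, first_id, method = "radix")[1]
  keep <- groups[[best]]
  excluded <- ids[setdiff(seq_along(ids), keep)]
  if (length(excluded) > 0) {
    warning("excluding ", length(excluded),
            " decoy(s) inconsistent with the majority sequence: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  structures <- structures[keep]
  if (length(structures) < 2) {
    stop_user("ensemble too small: fewer than 2 sequence-consistent decoys in ",
              dir)
  }
  structure(list(
    target_id = basename(normalizePath(dir)),
    structures = structures,
    common_length = structures[[1]]$length,
    n = length(structures),
    excluded = excluded
  ), class = "rna_ensemble")
}

#' @export
print.rna_ensemble <- function(x, ...) {
  cat(sprintf("<rna_ensemble> %s: %d decoys of %d nt\n",
              x$target_id, x$n, x$common_length))
  invisible(x)
}

ensemble_ids <- function(e) vapply(e$structures, `[[`, character(1), "id")
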