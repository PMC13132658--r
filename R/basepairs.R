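# Base-pair extraction (2D structure) from 3D coordinates and the
# Interaction Network Fidelity (INF) agreement score between two pair maps.

# Hydrogen-bond donor/acceptor heavy atoms on the base edges.
BASE_DONORS <- list(A = "N6", G = c("N1", "N2"), C = "N4", U = "N3")
BASE_ACCEPTORS <- list(A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
                       C = c("N3", "O2"), U = c("O2", "O4"))

BP_CATEGORIES <- c("canonical_wc", "wobble", "noncanonical")

#' Base-pair map constructor
#'
#' Validates and normalizes a set of residue-index pairs for one structure:
#' indices are 1-based ordered so `i < j`, near-adjacent pairs
#' (`j - i < min_separation`) are rejected, duplicates collapse (set
#' semantics).
#'
#' @param structure_id Decoy identifier.
#' @param length Residue count of the structure.
#' @param pairs Data frame with columns `i`, `j`, `category` (one of
#'   `canonical_wc`, `wobble`, `noncanonical`) and optionally `detail`.
#' @param min_separation Minimum sequence separation `j - i` (default 2).
#' @param chains Optional per-residue chain ids; when given, the separation
#'   rule applies only to same-chain pairs (separation across a chain break
#'   is not meaningful).
#' @return A `basepair_map`.
#' @export
basepair_map <- function(structure_id, length, pairs = NULL,
                         min_separation = 2L, chains = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    pairs <- data.frame(i = integer(0), j = integer(0),
                        category = character(0), detail = character(0),
                        stringsAsFactors = FALSE)
  } else {
    if (!"detail" %in% names(pairs)) pairs$detail <- ""
    lo <- pmin(pairs$i, pairs$j); hi <- pmax(pairs$i, pairs$j)
    pairs$i <- lo; pairs$j <- hi
    if (any(lo < 1 | hi > length)) {
      stop_user("base pair index out of range 1..", length, " in ",
                structure_id)
    }
    same_chain <- if (is.null(chains)) rep(TRUE, nrow(pairs))
      else chains[lo] == chains[hi]
    if (any(same_chain & (hi - lo < min_separation))) {
      stop_user("near-adjacent base pair (separation < ", min_separation,
                ") in ", structure_id)
    }
    if (!all(pairs$category %in% BP_CATEGORIES)) {
      stop_user("unknown base pair category in ", structure_id)
    }
    pairs <- pairs[!duplicated(pairs[, c("i", "j")]), , drop = FALSE]
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(structure_id = structure_id, length = length, pairs = pairs),
            class = "basepair_map")
}

#' @export
print.basepair_map <- function(x, ...) {
  cat(sprintf("<basepair_map> %s: %d pairs over %d nt\n",
              x$structure_id, nrow(x$pairs), x$length))
  invisible(x)
}

#' Geometric base-pair detection criteria
#'
#' Thresholds for [annotate_base_pairs()]: a residue pair (i, j) is annotated
#' as paired when its C1'-C1' distance lies within `[c1p_min, c1p_max]`, at
#' least `min_contacts` donor-acceptor heavy-atom contacts between the base
#' edges are within `hbond_max`, the angle between the base planes is at most
#' `max_plane_angle`, and `j - i >= min_separation`.
#'
#' @param c1p_min,c1p_max C1'-C1' distance window (Angstrom).
#' @param hbond_max Donor-acceptor contact cutoff (Angstrom).
#' @param min_contacts Minimum number of donor-acceptor contacts.
#' @param max_plane_angle Maximum base-plane angle (degrees).
#' @param min_separation Minimum sequence separation.
#' @return A `bp_criteria` list.
#' @export
bp_criteria <- function(c1p_min = 8, c1p_max = 12, hbond_max = 3.5,
                        min_contacts = 2L, max_plane_angle = 65,
                        min_separation = 2L) {
  structure(list(c1p_min = c1p_min, c1p_max = c1p_max, hbond_max = hbond_max,
                 min_contacts = min_contacts,
                 max_plane_angle = max_plane_angle,
                 min_separation = min_separation),
            class = "bp_criteria")
}

# Unit normal of the best-fit plane through >= 3 ring atoms.
base_plane_normal <- function(coords) {
  if (is.null(coords) || nrow(coords) < 3) return(NULL)
  centered <- sweep(coords, 2, colMeans(coords))
  svd(centered)$v[, 3]
}

#' Annotate base pairs from 3D geometry
#'
#' A built-in geometric annotator standing in for external tools (MC-annotate,
#' FR3D, RNAView): pairs are detected from C1' proximity, donor-acceptor
#' contact counts between base edges, and base-plane coplanarity (see
#' [bp_criteria()]). A-U / G-C pairs with Watson-Crick N1-N3 contact geometry
#' are labelled `canonical_wc`, G-U pairs `wobble`, everything else
#' `noncanonical`. Residues lacking base ring atoms stay unpaired (reported
#' once per structure). A base may participate in several pairs (triples are
#' real in RNA); the output is invariant under rigid motions of the structure.
#'
#' @param s An `rna_structure`.
#' @param criteria A [bp_criteria()].
#' @return A [basepair_map()].
#' @export
annotate_base_pairs <- function(s, criteria = bp_criteria()) {
  L <- s$length
  c1 <- matrix(NA_real_, L, 3)
  normals <- vector("list", L)
  edge <- vector("list", L)  # list(donors = matrix, acceptors = matrix)
  n_missing <- 0L
  for (k in seq_len(L)) {
    a <- s$atoms[[k]]
    if ("C1'" %in% rownames(a)) c1[k, ] <- a["C1'", ]
    ring <- a[rownames(a) %in% ring_atoms(s$bases[k]), , drop = FALSE]
    nrm <- base_plane_normal(ring)
    if (is.null(nrm)) {
      n_missing <- n_missing + 1L
      next
    }
    normals[[k]] <- nrm
    don <- a[rownames(a) %in% BASE_DONORS[[s$bases[k]]], , drop = FALSE]
    acc <- a[rownames(a) %in% BASE_ACCEPTORS[[s$bases[k]]], , drop = FALSE]
    edge[[k]] <- list(donors = don, acceptors = acc)
  }
  if (n_missing > 0) {
    message(s$id, ": ", n_missing,
            " residue(s) lack base atoms and stay unpaired")
  }
  rows <- list()
  usable <- which(!vapply(normals, is.null, logical(1)) &
                    stats::complete.cases(c1))
  if (length(usable) >= 2) {
    cmb <- utils::combn(usable, 2)
    for (col in seq_len(ncol(cmb))) {
      i <- cmb[1, col]; j <- cmb[2, col]
      if (s$chain[i] == s$chain[j] && j - i < criteria$min_separation) next
      dc <- sqrt(sum((c1[i, ] - c1[j, ])^2))
      if (dc < criteria$c1p_min || dc > criteria$c1p_max) next
      ang <- acos(min(1, abs(sum(normals[[i]] * normals[[j]])))) * 180 / pi
      if (ang > criteria$max_plane_angle) next
      n_contacts <- count_contacts(edge[[i]], edge[[j]], criteria$hbond_max)
      if (n_contacts < criteria$min_contacts) next
      rows[[length(rows) + 1L]] <-
        data.frame(i = i, j = j,
                   category = classify_pair(s, i, j, criteria$hbond_max),
                   detail = sprintf("%s-%s", s$bases[i], s$bases[j]),
                   stringsAsFactors = FALSE)
    }
  }
  basepair_map(s$id, L,
               if (length(rows)) do.call(rbind, rows) else NULL,
               min_separation = criteria$min_separation, chains = s$chain)
}

count_contacts <- function(edge_i, edge_j, cutoff) {
  n <- 0L
  n <- n + count_cross(edge_i$donors, edge_j$acceptors, cutoff)
  n + count_cross(edge_j$donors, edge_i$acceptors, cutoff)
}

count_cross <- function(xs, ys, cutoff) {
  if (is.null(xs) || is.null(ys) || nrow(xs) == 0 || nrow(ys) == 0) return(0L)
  d2 <- outer(rowSums(xs^2), rowSums(ys^2), `+`) - 2 * xs %*% t(ys)
  sum(d2 <= cutoff^2)
}

classify_pair <- function(s, i, j, hbond_max) {
  bi <- s$bases[i]; bj <- s$bases[j]
  pair <- paste(sort(c(bi, bj)), collapse = "")
  if (pair == "GU") return("wobble")
  if (pair %in% c("AU", "CG")) {
    pur <- if (is_purine(bi)) i else j
    pyr <- if (pur == i) j else i
    ap <- s$atoms[[pur]]; ay <- s$atoms[[pyr]]
    if ("N1" %in% rownames(ap) && "N3" %in% rownames(ay)) {
      d <- sqrt(sum((ap["N1", ] - ay["N3", ])^2))
      if (d <= hbond_max) return("canonical_wc")
    }
  }
  "noncanonical"
}

#' Read an external base-pair annotation file
#'
#' Pair-list format: one pair per line, whitespace separated, `'#'` comments.
#' The default dialect is `i j label` with 1-based residue indices; FR3D- and
#' RNAView-style pair lines are tolerated by taking the first two integer
#' tokens on the line as the residue indices and the first remaining
#' non-numeric token as the label. Labels `WC`, `cWW`, `+/+`, `-/-` map to
#' `canonical_wc`; `GU` or `wobble` to `wobble`; anything else to
#' `noncanonical`. Duplicate pairs collapse.
#'
#' @param path Annotation file.
#' @param length Residue count of the annotated structure.
#' @param structure_id Identifier; default file name without extension.
#' @param dialect `"basic"`, `"fr3d"` or `"rnaview"` (parsed identically;
#'   kept for provenance).
#' @return A [basepair_map()].
#' @export
read_pair_annotation <- function(path, length,
                                 structure_id = NULL,
                                 dialect = c("basic", "fr3d", "rnaview")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_user("no such annotation file: ", path)
  structure_id <- structure_id %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln_no in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[ln_no])
    if (!nzchar(trimws(ln))) next
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    ints <- suppressWarnings(as.integer(toks))
    int_pos <- which(!is.na(ints) & !grepl("[^0-9]", toks))
    if (length(int_pos) < 2) {
      stop_user("malformed pair line ", ln_no, " in ", path,
                ": need two residue indices")
    }
    i <- ints[int_pos[1]]; j <- ints[int_pos[2]]
    lab_pos <- setdiff(seq_along(toks), int_pos[1:2])
    label <- if (length(lab_pos)) toks[lab_pos[1]] else ""
    if (i < 1 || j < 1 || i > length || j > length) {
      stop_user("pair (", i, ", ", j, ") out of range 1..", length,
                " at line ", ln_no, " in ", path)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      i = i, j = j, category = categorize_label(label), detail = label,
      stringsAsFactors = FALSE)
  }
  basepair_map(structure_id, length,
               if (length(rows)) do.call(rbind, rows) else NULL)
}

categorize_label <- function(label) {
  u <- toupper(label)
  if (u %in% c("WC", "CWW", "W/W", "+/+", "-/-", "WW", "CANONICAL",
               "CANONICAL_WC")) return("canonical_wc")
  if (u %in% c("GU", "WOBBLE", "WOB")) return("wobble")
  "noncanonical"
}

pair_keys <- function(map, strict_labels = FALSE) {
  p <- map$pairs
  if (nrow(p) == 0) return(character(0))
  if (strict_labels) paste(p$i, p$j, p$category) else paste(p$i, p$j)
}

#' Interaction Network Fidelity between two base-pair maps
#'
#' The geometric mean of base-pair precision and recall:
#' `sqrt(TP/(TP+FP) * TP/(TP+FN))`, where TP are pairs present in both maps,
#' FP pairs only in `a`, FN pairs only in `b`. Matching is on residue-index
#' pairs only (annotator label dialects differ); `strict_labels = TRUE`
#' additionally requires matching categories. Two empty maps agree perfectly
#' (INF 1, configurable via `both_empty`); exactly one empty map scores 0.
#'
#' @param a,b `basepair_map` objects over structures of identical length.
#' @param strict_labels Match categories as well as indices.
#' @param both_empty Value when both maps are empty.
#' @return Similarity in [0, 1]; symmetric in `a`, `b`.
#' @export
inf_score <- function(a, b, strict_labels = FALSE, both_empty = 1) {
  if (a$length != b$length) {
    stop_user("correspondence error: base pair maps have different lengths (",
              a$length, " vs ", b$length, ")")
  }
  ka <- pair_keys(a, strict_labels)
  kb <- pair_keys(b, strict_labels)
  if (length(ka) == 0 && length(kb) == 0) return(both_empty)
  if (length(ka) == 0 || length(kb) == 0) return(0)
  tp <- length(intersect(ka, kb))
  if (tp == 0) return(0)
  fp <- length(setdiff(ka, kb))
  fn <- length(setdiff(kb, ka))
  sqrt((tp / (tp + fp)) * (tp / (tp + fn)))
}
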