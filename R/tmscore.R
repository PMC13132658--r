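# Pairwise TM-score between equal-length RNA decoys: Kabsch superposition
# plus an iterative fragment-seeded search for the score-optimal alignment.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid transform mapping `coords_a` onto `coords_b`.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices, n >= 3, same n.
#' @return List with `rotation` (proper 3 x 3), `translation` (length 3),
#'   `rmsd` (Angstrom, the minimum over all rigid transforms) and
#'   `aligned_indices`. The transform maps a point `p` of `coords_a` to
#'   `rotation %*% p + translation`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  n <- nrow(coords_a)
  if (n != nrow(coords_b)) stop_user("superposition: point counts differ")
  if (n < 3) stop_user("degenerate superposition: need at least 3 points")
  if (!all(is.finite(coords_a)) || !all(is.finite(coords_b))) {
    stop_user("superposition: non-finite coordinates")
  }
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- crossprod(A, B)                     # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  resid <- A %*% t(R) - B
  list(
    rotation = R,
    translation = as.numeric(cb - R %*% ca),
    rmsd = sqrt(sum(resid^2) / n),
    aligned_indices = seq_len(n)
  )
}

#' TM-score distance scale d0 for RNA
#'
#' The RNA length-dependent scale used in the TM-score term
#' 1 / (1 + (d/d0)^2): `0.6 * sqrt(L - 0.5) - 2.5`, clamped below at `floor`.
#'
#' @param L Normalization length (residues), >= 1.
#' @param floor Lower clamp in Angstrom.
#' @return d0 in Angstrom; non-decreasing in `L`.
#' @export
default_d0 <- function(L, floor = 0.3) {
  stopifnot(L >= 1)
  pmax(floor, 0.6 * sqrt(pmax(L - 0.5, 0)) - 2.5)
}

#' TM-score parameters
#'
#' @param L_norm Normalization length; for ensemble scoring this is the common
#'   target length so the pairwise matrix is symmetric.
#' @param d0 Distance scale (Angstrom); default [default_d0()] of `L_norm`.
#' @param representative_atom Atom-name fallback order for the residue trace.
#' @return A `tm_params` list.
#' @export
tm_params <- function(L_norm, d0 = default_d0(L_norm),
                      representative_atom = c("C1'", "C4'", "P")) {
  stopifnot(d0 > 0, L_norm >= 1)
  structure(list(d0 = d0, L_norm = L_norm,
                 representative_atom = representative_atom),
            class = "tm_params")
}

# d_cut schedule for the iterative alignment refinement (Angstrom).
TM_DCUT_SCHEDULE <- c(8, 7, 6, 5, 4.5)
TM_MAX_ITER <- 20L

# Contiguous fragment seeds over n aligned positions. Up to `dense_limit`
# positions, every fragment of length >= 4 is used (the compiled search makes
# this cheap, and it is what guarantees score-optimal alignments on short
# chains). On longer chains, fragments of length n, n/2, n/4, ... (min 4) at
# stride max(1, n/10) keep the search near-linear.
tm_seeds <- function(n, dense_limit = 60L) {
  seeds <- list()
  if (n <= dense_limit) {
    for (len in seq.int(4L, n)) {
      for (start in seq_len(n - len + 1L)) {
        seeds[[length(seeds) + 1L]] <- seq.int(start, start + len - 1L)
      }
    }
    return(seeds)
  }
  lens <- n
  while (lens[length(lens)] > 4L) {
    lens <- c(lens, max(4L, as.integer(floor(lens[length(lens)] / 2))))
  }
  stride <- max(1L, as.integer(floor(n / 10)))
  for (len in unique(lens)) {
    for (start in seq(1L, n - len + 1L, by = stride)) {
      seeds[[length(seeds) + 1L]] <- seq.int(start, start + len - 1L)
    }
  }
  unique(seeds)
}

#' TM-score between two equal-length RNA decoys
#'
#' Computes max over searched superpositions of
#' `(1/L_norm) * sum_k 1 / (1 + (d_k/d0)^2)`, where `d_k` is the distance
#' between corresponding representative atoms (C1', falling back to C4' then
#' P). Residues lacking the representative atom in either decoy are excluded
#' from the sum while `L_norm` is unchanged, so missing atoms penalize. The
#' search seeds the Kabsch superposition with contiguous fragments and
#' iteratively refines the aligned subset under a shrinking distance cutoff.
#'
#' @param a,b `rna_structure` objects of identical length (1:1 residue
#'   correspondence by position).
#' @param params A [tm_params()]; defaults to the common length with the RNA
#'   d0 formula.
#' @return Similarity in (0, 1]; `tm_score(a, a)` is 1 within 1e-9, and the
#'   score is symmetric and invariant under rigid motions of either input.
#' @export
tm_score <- function(a, b, params = NULL) {
  if (a$length != b$length) {
    stop_user("residue correspondence error: lengths differ (",
              a$length, " vs ", b$length, ")")
  }
  params <- params %||% tm_params(a$length)
  A_full <- rep_coords(a, params$representative_atom)
  B_full <- rep_coords(b, params$representative_atom)
  ok <- stats::complete.cases(A_full) & stats::complete.cases(B_full)
  if (sum(ok) < 3) stop_user("degenerate pair: fewer than 3 usable residues")
  A <- A_full[ok, , drop = FALSE]
  B <- B_full[ok, , drop = FALSE]
  best <- tm_search_cpp(A, B, tm_seeds(nrow(A)), params$d0, params$L_norm,
                        TM_DCUT_SCHEDULE, TM_MAX_ITER)
  min(best, 1)
}

#' Load a precomputed pairwise TM-score matrix
#'
#' Escape hatch for cross-checking against an external TM-score engine:
#' reads a CSV with columns `i`, `j`, `score` (decoy ids) and returns the
#' corresponding symmetric [similarity_matrix()].
#'
#' @param path CSV path.
#' @param ids Ordered decoy identifiers the matrix must cover.
#' @return A `similarity_matrix` of kind `"tm"`.
#' @export
tm_matrix_from_csv <- function(path, ids) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("i", "j", "score")
  if (!all(need %in% names(tab))) {
    stop_user("TM-score CSV must have columns i, j, score: ", path)
  }
  n <- length(ids)
  v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(v) <- 1
  bad <- !(tab$i %in% ids) | !(tab$j %in% ids)
  if (any(bad)) {
    stop_user("TM-score CSV refers to unknown decoy ids: ",
              paste(unique(c(tab$i[bad], tab$j[bad])), collapse = ", "))
  }
  v[cbind(tab$i, tab$j)] <- tab$score
  v[cbind(tab$j, tab$i)] <- tab$score
  if (any(is.na(v))) stop_user("TM-score CSV is missing entries for some pairs")
  similarity_matrix(ids, unname(v), kind = "tm")
}
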