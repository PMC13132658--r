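# The consensus core: all-vs-all similarity matrices over the ensemble
# (TM-score T, base-pair INF I), their element-wise product M = T * I, and
# per-decoy quality scores Q_i = mean_{j != i} M_ij.

#' Similarity matrix over an ensemble
#'
#' @param ids Ordered decoy identifiers.
#' @param values N x N numeric matrix, entries in [0, 1], symmetric, unit
#'   diagonal (the diagonal is a convention; quality scores never use it).
#' @param kind `"tm"`, `"inf"` or `"consensus"`.
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(ids, values, kind = c("tm", "inf", "consensus")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  n <- length(ids)
  stopifnot(nrow(values) == n, ncol(values) == n)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop_user("similarity values must be finite and in [0, 1]")
  }
  if (max(abs(values - t(values))) > 1e-9) {
    stop_user("similarity matrix must be symmetric")
  }
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, kind = kind),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<similarity_matrix> kind=%s, N=%d, off-diagonal range [%.3f, %.3f]\n",
              x$kind, length(x$ids),
              if (length(off)) min(off) else NA, if (length(off)) max(off) else NA))
  invisible(x)
}

#' All-vs-all pairwise similarity matrix
#'
#' Evaluates a symmetric pair measure once per unordered pair and mirrors the
#' result; the diagonal is set to 1. Work is partitioned over unordered pairs
#' into batches that may run on parallel workers; each cell is written once,
#' so the result is identical regardless of `jobs` and `batch`.
#'
#' @param objects List of per-decoy objects (e.g. `rna_structure` or
#'   `basepair_map`) in ensemble order.
#' @param ids Decoy identifiers, same order.
#' @param measure Function of two objects returning a similarity in [0, 1].
#' @param kind Matrix kind, see [similarity_matrix()].
#' @param jobs Worker count (forked processes when > 1).
#' @param batch Pairs per work unit; default splits evenly over workers.
#' @return A [similarity_matrix()].
#' @export
pairwise_matrix <- function(objects, ids, measure,
                            kind = c("tm", "inf", "consensus"),
                            jobs = 1L, batch = NULL) {
  kind <- match.arg(kind)
  n <- length(objects)
  stopifnot(length(ids) == n)
  if (n < 2) stop_user("pairwise matrix needs an ensemble of at least 2")
  pairs <- utils::combn(n, 2)
  npairs <- ncol(pairs)
  batch <- batch %||% max(1L, ceiling(npairs / max(1L, 4L * jobs)))
  chunk_of <- ceiling(seq_len(npairs) / batch)
  eval_chunk <- function(cols) {
    vapply(cols, function(col) {
      i <- pairs[1, col]; j <- pairs[2, col]
      # canonical argument order by id: a symmetric measure may still differ
      # by floating-point rounding under argument swap, and evaluating every
      # unordered pair the same way makes results exactly permutation-invariant
      if (ids[i] > ids[j]) { tmp <- i; i <- j; j <- tmp }
      tryCatch(measure(objects[[i]], objects[[j]]), error = function(e) {
        stop_user("pair evaluation failed for decoys '", ids[i], "' and '",
                  ids[j], "': ", conditionMessage(e))
      })
    }, numeric(1))
  }
  chunks <- split(seq_len(npairs), chunk_of)
  vals <- if (jobs > 1L) {
    res <- parallel::mclapply(chunks, eval_chunk, mc.cores = jobs,
                              mc.preschedule = FALSE)
    err <- vapply(res, inherits, logical(1), "try-error")
    if (any(err)) stop_user(attr(res[[which(err)[1]]], "condition")$message)
    unlist(res, use.names = FALSE)
  } else {
    unlist(lapply(chunks, eval_chunk), use.names = FALSE)
  }
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals))[1]
    stop_user("pair evaluation produced a non-finite value for decoys '",
              ids[pairs[1, bad]], "' and '", ids[pairs[2, bad]], "'")
  }
  v <- diag(1, n)
  v[t(pairs)] <- vals
  v[t(pairs[2:1, , drop = FALSE])] <- vals
  similarity_matrix(ids, v, kind = kind)
}

#' Element-wise product of two similarity matrices
#'
#' The consensus matrix `M_ij = T_ij * I_ij`: global 3D similarity reinforced
#' by 2D base-pairing agreement. `M_ij <= min(T_ij, I_ij)` always holds.
#'
#' @param T_mat,I_mat [similarity_matrix()] objects with identical ids in
#'   identical order.
#' @return A `similarity_matrix` of kind `"consensus"`.
#' @export
combine_similarity <- function(T_mat, I_mat) {
  if (!identical(T_mat$ids, I_mat$ids)) {
    stop_user("alignment error: similarity matrices have different ids/order")
  }
  v <- T_mat$values * I_mat$values
  diag(v) <- 1
  similarity_matrix(T_mat$ids, v, kind = "consensus")
}

#' Per-decoy consensus quality scores
#'
#' `Q_i` is the mean agreement of decoy i with all other decoys: the
#' off-diagonal row mean of the consensus matrix. With the TM-score matrix in
#' place of the consensus matrix this is the no-base-pair baseline variant.
#'
#' @param m A [similarity_matrix()] (consensus matrix, or the TM matrix for
#'   the `no_bp` variant).
#' @param variant Label: `"consensus"` (T * I) or `"no_bp"` (T only).
#' @return A `quality_scores` object: `ids`, `q` in [0, 1], `variant`.
#' @export
quality_scores <- function(m, variant = c("consensus", "no_bp")) {
  variant <- match.arg(variant)
  v <- m$values
  n <- nrow(v)
  if (n < 2) stop_user("quality scores need at least 2 decoys")
  q <- vapply(seq_len(n), function(i) sum(v[i, -i]) / (n - 1), numeric(1))
  structure(list(ids = m$ids, q = unname(q), variant = variant),
            class = "quality_scores")
}

#' @export
print.quality_scores <- function(x, ...) {
  cat(sprintf("<quality_scores> variant=%s, N=%d, best=%s (Q=%.4f)\n",
              x$variant, length(x$ids),
              x$ids[order(-x$q, x$ids)[1]], max(x$q)))
  invisible(x)
}

#' Rank decoys by quality score
#'
#' Sorts decoys by Q descending; ties are broken lexicographically by decoy
#' id so rankings are reproducible.
#'
#' @param qs A [quality_scores()] object.
#' @return Data frame `decoy_id`, `q`, `rank` in rank order.
#' @export
rank_decoys <- function(qs) {
  ord <- order(-qs$q, qs$ids, method = "radix")
  data.frame(decoy_id = qs$ids[ord], q = qs$q[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Score an RNA decoy ensemble by pairwise consensus
#'
#' The end-to-end method: builds the pairwise TM-score matrix T (fragment-
#' seeded superposition search), extracts per-decoy base-pair maps (built-in
#' geometric annotator, or external pair-list annotations when provided),
#' builds the pairwise INF matrix I, forms the consensus matrix M = T * I,
#' and returns per-decoy quality scores for both variants: `consensus`
#' (with base-pair emphasis) and `no_bp` (TM-score agreement alone). Higher
#' scores mean a decoy is consistently supported by both the 3D fold and the
#' 2D base-pairing pattern of the ensemble.
#'
#' @param e An `rna_ensemble` from [read_ensemble()].
#' @param annotations Optional directory of per-decoy pair-list files named
#'   `<decoy_id>.*`; when `NULL` the built-in annotator is used.
#' @param tm_csv Optional precomputed pairwise TM-score CSV (`i,j,score`)
#'   replacing the internal TM-score engine.
#' @param criteria [bp_criteria()] for the built-in annotator.
#' @param params [tm_params()]; defaults to the ensemble's common length.
#' @param strict_labels Match base-pair categories in INF, not just indices.
#' @param inf_floor Lower bound applied to the INF matrix before the
#'   element-wise product (default 0.1). An empty or wholly non-overlapping
#'   pair map carries no usable 2D evidence; without a floor such a decoy's
#'   consensus row is annihilated (M = 0) no matter how good its 3D
#'   agreement is, so the floor makes it fall back to down-weighted TM-score
#'   consensus instead. Whenever every decoy has a non-degenerate
#'   annotation -- the realistic case -- the floor never binds and the
#'   consensus matrix is exactly the element-wise product. Set to 0 for the
#'   strict product.
#' @param jobs,batch Parallelization of the pairwise computations, see
#'   [pairwise_matrix()].
#' @return An `ensemble_scores` list: `scores` (data frame with `decoy_id`,
#'   `Q_consensus`, `Q_no_bp`, `rank` by the consensus variant),
#'   `q_consensus`, `q_no_bp`, and the three matrices `T`, `I`, `M`.
#' @export
score_ensemble <- function(e, annotations = NULL, tm_csv = NULL,
                           criteria = bp_criteria(), params = NULL,
                           strict_labels = FALSE, inf_floor = 0.1,
                           jobs = 1L, batch = NULL) {
  stopifnot(inf_floor >= 0, inf_floor <= 1)
  stopifnot(inherits(e, "rna_ensemble"))
  ids <- ensemble_ids(e)
  params <- params %||% tm_params(e$common_length)
  T_mat <- if (!is.null(tm_csv)) {
    tm_matrix_from_csv(tm_csv, ids)
  } else {
    pairwise_matrix(e$structures, ids,
                    function(a, b) tm_score(a, b, params),
                    kind = "tm", jobs = jobs, batch = batch)
  }
  maps <- if (!is.null(annotations)) {
    load_annotations(annotations, ids, e$common_length)
  } else {
    lapply(e$structures, annotate_base_pairs, criteria = criteria)
  }
  I_mat <- pairwise_matrix(maps, ids,
                           function(a, b) inf_score(a, b, strict_labels),
                           kind = "inf", jobs = jobs, batch = batch)
  I_eff <- if (inf_floor > 0) {
    similarity_matrix(ids, pmax(I_mat$values, inf_floor), kind = "inf")
  } else I_mat
  M <- combine_similarity(T_mat, I_eff)
  qc <- quality_scores(M, "consensus")
  qn <- quality_scores(T_mat, "no_bp")
  ranking <- rank_decoys(qc)
  scores <- data.frame(decoy_id = ids,
                       Q_consensus = qc$q,
                       Q_no_bp = qn$q,
                       stringsAsFactors = FALSE)
  scores$rank <- ranking$rank[match(scores$decoy_id, ranking$decoy_id)]
  structure(list(scores = scores, q_consensus = qc, q_no_bp = qn,
                 T = T_mat, I = I_mat, M = M),
            class = "ensemble_scores")
}

#' @export
print.ensemble_scores <- function(x, ...) {
  cat(sprintf("<ensemble_scores> %d decoys\n", nrow(x$scores)))
  top <- x$scores[order(x$scores$rank), ][seq_len(min(5, nrow(x$scores))), ]
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

load_annotations <- function(dir, ids, length) {
  if (!dir.exists(dir)) stop_user("no such annotation directory: ", dir)
  files <- list.files(dir, full.names = TRUE)
  stems <- tools::file_path_sans_ext(basename(files))
  lapply(ids, function(id) {
    hit <- which(stems == id)
    if (length(hit) == 0) {
      stop_user("no annotation file for decoy '", id, "' in ", dir)
    }
    read_pair_annotation(files[hit[1]], length, structure_id = id)
  })
}

#' Write ensemble scores and matrices to CSV
#'
#' `scores.csv` has columns `decoy_id,Q_consensus,Q_no_bp,rank`;
#' `matrices.csv` is long-format `i,j,kind,value` over all three matrices.
#' Values are printed with 6 decimals.
#'
#' @param res An `ensemble_scores` from [score_ensemble()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_scores <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- res$scores
  sc$Q_consensus <- sprintf("%.6f", sc$Q_consensus)
  sc$Q_no_bp <- sprintf("%.6f", sc$Q_no_bp)
  scores_path <- file.path(dir, "scores.csv")
  utils::write.csv(sc, scores_path, row.names = FALSE, quote = FALSE)
  long <- do.call(rbind, lapply(list(res$T, res$I, res$M), function(m) {
    idx <- which(upper.tri(m$values), arr.ind = TRUE)
    data.frame(i = m$ids[idx[, 1]], j = m$ids[idx[, 2]], kind = m$kind,
               value = sprintf("%.6f", m$values[idx]),
               stringsAsFactors = FALSE)
  }))
  mat_path <- file.path(dir, "matrices.csv")
  utils::write.csv(long, mat_path, row.names = FALSE, quote = FALSE)
  invisible(c(scores_path, mat_path))
}
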