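make_test_ensemble <- function(n = 4, sigma = 0.5, n_bp = 8, seed = 1) {
  ref <- ideal_duplex(n_bp)$structure
  structures <- lapply(seq_len(n), function(k) {
    perturb_structure(ref, sigma, seed = seed * 100 + k,
                      id = sprintf("d%02d", k))
  })
  structure(list(target_id = "fixture", structures = structures,
                 common_length = ref$length, n = n, excluded = character(0)),
            class = "rna_ensemble")
}

test_that("identical decoys give an all-ones matrix and unit quality", {
  ref <- ideal_duplex(6)$structure
  e <- make_test_ensemble(3, sigma = 0)
  m <- pairwise_matrix(e$structures, c("d01", "d02", "d03"),
                       function(a, b) tm_score(a, b), kind = "tm")
  expect_equal(unname(m$values), matrix(1, 3, 3), tolerance = 1e-9)
  res <- score_ensemble(e)
  expect_equal(res$scores$Q_consensus, rep(1, 3), tolerance = 1e-6)
  expect_equal(res$scores$Q_no_bp, rep(1, 3), tolerance = 1e-6)
})

test_that("pairwise matrices are identical across worker counts", {
  e <- make_test_ensemble(4)
  ids <- sprintf("d%02d", 1:4)
  m1 <- pairwise_matrix(e$structures, ids, function(a, b) tm_score(a, b),
                        kind = "tm", jobs = 1)
  m4 <- pairwise_matrix(e$structures, ids, function(a, b) tm_score(a, b),
                        kind = "tm", jobs = 4, batch = 2)
  expect_identical(m1$values, m4$values)
})

test_that("the INF matrix equals a naive double loop", {
  e <- make_test_ensemble(5, sigma = 0.3)
  maps <- lapply(e$structures, annotate_base_pairs)
  ids <- sprintf("d%02d", 1:5)
  m <- pairwise_matrix(maps, ids, function(a, b) inf_score(a, b),
                       kind = "inf")
  naive <- diag(1, 5)
  for (i in 1:5) for (j in 1:5) {
    if (i != j) naive[i, j] <- inf_score(maps[[i]], maps[[j]])
  }
  expect_equal(unname(m$values), naive)
})

test_that("pair evaluation failures name both decoys", {
  e <- make_test_ensemble(3)
  expect_error(
    pairwise_matrix(e$structures, c("a", "b", "c"),
                    function(x, y) stop("boom"), kind = "tm"),
    "'a' and 'b'")
})

test_that("combine multiplies element-wise with the product bound", {
  ids <- c("x", "y", "z")
  Tv <- random_similarity_values(3)
  Tm <- similarity_matrix(ids, Tv, "tm")
  ones <- similarity_matrix(ids, matrix(1, 3, 3), "inf")
  expect_equal(combine_similarity(Tm, ones)$values, Tm$values)

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    idn <- sprintf("s%d", 1:n)
    A <- similarity_matrix(idn, random_similarity_values(n), "tm")
    B <- similarity_matrix(idn, random_similarity_values(n), "inf")
    M <- combine_similarity(A, B)
    expect_true(all(M$values <= pmin(A$values, B$values) + 1e-12))
  }
  expect_error(combine_similarity(Tm, similarity_matrix(c("x", "z", "y"),
                                                        Tv, "inf")),
               "alignment")
})

test_that("quality scores reproduce the naive Eq-by-Eq oracle bit-identically", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(2:20, 1)
    ids <- sprintf("s%02d", 1:n)
    Tv <- random_similarity_values(n)
    Iv <- random_similarity_values(n)
    M <- combine_similarity(similarity_matrix(ids, Tv, "tm"),
                            similarity_matrix(ids, Iv, "inf"))
    q <- quality_scores(M, "consensus")
    expect_identical(q$q, oracle_consensus_q(Tv, Iv))
    # product bound: consensus never exceeds the TM-only baseline
    qn <- quality_scores(similarity_matrix(ids, Tv, "tm"), "no_bp")
    expect_true(all(q$q <= qn$q + 1e-12))
  }
})

test_that("hand-sized quality arithmetic is exact", {
  ids <- c("a", "b", "c")
  v <- matrix(c(1, 0.2, 0.4, 0.2, 1, 0.6, 0.4, 0.6, 1), 3, 3)
  q <- quality_scores(similarity_matrix(ids, v, "consensus"))
  expect_equal(q$q[1], 0.3)
})

test_that("scoring is permutation-equivariant", {
  e <- make_test_ensemble(5, sigma = 0.8)
  res <- score_ensemble(e)
  perm <- c(3, 1, 5, 2, 4)
  ep <- e
  ep$structures <- e$structures[perm]
  resp <- score_ensemble(ep)
  expect_identical(resp$scores$Q_consensus, res$scores$Q_consensus[perm])
  expect_identical(resp$scores$Q_no_bp, res$scores$Q_no_bp[perm])
})

test_that("adding an exact duplicate never decreases that decoy's quality", {
  e <- make_test_ensemble(4, sigma = 1)
  res <- score_ensemble(e)
  dup <- e$structures[[2]]
  dup$id <- "d99"
  e2 <- e
  e2$structures <- c(e$structures, list(dup))
  e2$n <- 5
  res2 <- score_ensemble(e2)
  expect_gte(res2$scores$Q_consensus[2] + 1e-12, res$scores$Q_consensus[2])
})

test_that("ranking breaks ties lexicographically by decoy id", {
  qs <- structure(list(ids = c("zeta", "alpha", "mid"),
                       q = c(0.5, 0.5, 0.7), variant = "consensus"),
                  class = "quality_scores")
  r <- rank_decoys(qs)
  expect_equal(r$decoy_id, c("mid", "alpha", "zeta"))
  expect_equal(r$rank, 1:3)
})

test_that("scores CSV output is byte-identical across runs and workers", {
  e <- make_test_ensemble(4, sigma = 0.7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scores(score_ensemble(e, jobs = 1), d1)
  write_scores(score_ensemble(e, jobs = 4, batch = 1), d2)
  expect_identical(readLines(file.path(d1, "scores.csv")),
                   readLines(file.path(d2, "scores.csv")))
  expect_identical(readLines(file.path(d1, "matrices.csv")),
                   readLines(file.path(d2, "matrices.csv")))
})

test_that("external annotations can replace the built-in annotator", {
  e <- make_test_ensemble(3, sigma = 0, n_bp = 6)
  ann <- withr::local_tempdir()
  for (id in sprintf("d%02d", 1:3)) {
    writeLines(c("1 12 WC", "2 11 WC", "3 10 WC"), file.path(ann, paste0(id, ".txt")))
  }
  res <- score_ensemble(e, annotations = ann)
  expect_equal(unname(res$I$values), matrix(1, 3, 3))
  expect_error(score_ensemble(e, annotations = withr::local_tempdir()),
               "no annotation file")
})

test_that("base-pair disruption demotes a decoy only under the consensus variant", {
  n_bp <- 15
  ref <- ideal_duplex(n_bp)
  sigma <- 0.15
  structures <- c(
    lapply(1:5, function(k) {
      perturb_structure(ref$structure, sigma, seed = 800 + k,
                        id = sprintf("intact_%02d", k))
    }),
    list(perturb_structure(
      disrupt_pairs(ref$structure, ref$pairs, 0.5, seed = 900),
      sigma, seed = 806, id = "flipped")))
  e <- structure(list(target_id = "ablation", structures = structures,
                      common_length = ref$structure$length, n = 6,
                      excluded = character(0)), class = "rna_ensemble")
  res <- score_ensemble(e)
  sc <- res$scores
  flipped <- sc$decoy_id == "flipped"
  expect_true(all(sc$Q_consensus[flipped] < sc$Q_consensus[!flipped]))
  expect_lt(abs(sc$Q_no_bp[flipped] - median(sc$Q_no_bp)), 0.02)
})
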