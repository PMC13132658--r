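test_that("the annotator recovers exactly the designed duplex pairing", {
  d <- ideal_duplex(8)
  bp <- annotate_base_pairs(d$structure)
  expect_equal(nrow(bp$pairs), 8)
  expect_setequal(paste(bp$pairs$i, bp$pairs$j), paste(d$pairs$i, d$pairs$j))
  expect_true(all(bp$pairs$category == "canonical_wc"))
})

test_that("extended strands and separated strands have no pairs", {
  expect_equal(nrow(annotate_base_pairs(extended_strand(10))$pairs), 0)
  d <- ideal_duplex(8)$structure
  # translate one strand far away: distance precondition fails everywhere
  far <- d
  for (k in which(far$chain == "B")) {
    far$atoms[[k]] <- far$atoms[[k]] + 30
  }
  expect_equal(nrow(annotate_base_pairs(far)$pairs), 0)
})

test_that("annotation is invariant under rigid motions", {
  d <- ideal_duplex(7)$structure
  bp0 <- annotate_base_pairs(d)
  bp1 <- annotate_base_pairs(rigid_move(d, rot_z(118), c(8, -3, 12)))
  expect_equal(bp0$pairs[, c("i", "j", "category")],
               bp1$pairs[, c("i", "j", "category")])
})

test_that("a constructed G.U pair is annotated as wobble", {
  # G in the standard pair frame, U on the complementary side shifted into
  # the major groove so the two wobble hydrogen bonds (N1-O2, O6-N3) form;
  # a far-away spacer residue keeps the sequence separation valid.
  g <- base_frame_atoms("G")
  u <- base_frame_atoms("U") %*% diag(c(1, -1, -1))
  rownames(u) <- rownames(base_frame_atoms("U"))
  u <- sweep(u, 2, c(0.486, 0.862, 0), `+`)
  spacer <- base_frame_atoms("A") + 60
  s <- make_residue_structure("wobble_fixture", c("G", "A", "U"),
                              rep("A", 3), 1:3, list(g, spacer, u))
  bp <- annotate_base_pairs(s)
  expect_equal(nrow(bp$pairs), 1)
  expect_equal(bp$pairs$i, 1)
  expect_equal(bp$pairs$j, 3)
  expect_equal(bp$pairs$category, "wobble")
})

test_that("pair-list files parse with 1-based validation", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# designed pairs", "1 8 WC", "2 7 WC"), f)
  m <- read_pair_annotation(f, length = 8)
  expect_equal(nrow(m$pairs), 2)
  expect_true(all(m$pairs$category == "canonical_wc"))

  writeLines(c("0 5 WC"), f)
  expect_error(read_pair_annotation(f, length = 8), "out of range")

  writeLines(c("1 8 WC", "1 8 WC"), f)
  expect_equal(nrow(read_pair_annotation(f, length = 8)$pairs), 1)

  writeLines(c("1 8 WC", "oops"), f)
  expect_error(read_pair_annotation(f, length = 8), "line 2")
})

test_that("INF matches its defining arithmetic on small cases", {
  mk <- function(pairs, len = 8, id = "x") {
    basepair_map(id, len, data.frame(i = pairs[, 1], j = pairs[, 2],
                                     category = "canonical_wc"))
  }
  a <- mk(rbind(c(1, 8), c(2, 7)))
  expect_equal(inf_score(a, a), 1)
  b3 <- mk(rbind(c(1, 8), c(2, 7), c(3, 6)))
  expect_equal(inf_score(b3, a), sqrt(2 / 3))
  expect_equal(inf_score(mk(rbind(c(1, 8))), mk(rbind(c(4, 7)))), 0)
  empty <- basepair_map("e", 8)
  expect_equal(inf_score(empty, empty), 1)
  expect_equal(inf_score(empty, empty, both_empty = 0), 0)
  expect_equal(inf_score(a, empty), 0)
  expect_error(inf_score(a, basepair_map("y", 9)), "correspondence")
})

test_that("INF equals the set-enumeration oracle on random map pairs", {
  set.seed(101)
  for (rep in 1:200) {
    len <- sample(8:30, 1)
    a <- random_map(len, sample(0:10, 1))
    b <- random_map(len, sample(0:10, 1))
    expect_identical(inf_score(a, b), oracle_inf(a, b))
    # precision/recall duality: swapping arguments swaps FP and FN only
    expect_identical(inf_score(a, b), inf_score(b, a))
  }
})

test_that("strict label matching distinguishes categories", {
  a <- basepair_map("a", 8, data.frame(i = 1, j = 8, category = "canonical_wc"))
  b <- basepair_map("b", 8, data.frame(i = 1, j = 8, category = "wobble"))
  expect_equal(inf_score(a, b), 1)
  expect_equal(inf_score(a, b, strict_labels = TRUE), 0)
})
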