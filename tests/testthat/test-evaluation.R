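test_that("the composite score is the exact weighted sum", {
  expect_equal(composite_score(1, 1, 1), 1)
  expect_equal(composite_score(0, 0, 0), 0)
  expect_equal(composite_score(0.8, 0.6, 0.7), 0.3 * 0.8 + 0.3 * 0.6 + 0.4 * 0.7)
  expect_error(composite_score(0.5, NA, 0.5), "missing")
  expect_error(composite_score(0.5, 1.2, 0.5), "\\[0, 1\\]")
})

test_that("min-max normalization maps to [0,1] with the midpoint convention", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0.5, 0.5, 0.5))
  x <- c(0.2, 1.4, -3, 7)
  expect_equal(minmax_normalize(3 * x + 11), minmax_normalize(x))
  expect_error(minmax_normalize(4), ">= 2")
})

test_that("score orientation is an involution on lower-better inputs", {
  expect_equal(negate_if_energy(c(-3.2, -1.0), "lower_better"), c(3.2, 1.0))
  expect_equal(negate_if_energy(c(1, 2), "higher_better"), c(1, 2))
  expect_equal(negate_if_energy(negate_if_energy(c(1, 2), "lower_better"),
                                "lower_better"), c(1, 2))
})

test_that("top-1 loss follows its definition, with reproducible ties", {
  expect_equal(top1_loss(c(0.9, 0.1), c(0.9, 0.6)), 0)
  expect_equal(top1_loss(c(0.1, 0.7), c(0.9, 0.6)), 0.3)
  set.seed(201)
  for (rep in 1:100) {
    n <- sample(2:15, 1)
    p <- runif(n); y <- runif(n)
    expect_equal(top1_loss(p, y), oracle_top1(p, y))
  }
  # ties in predicted break lexicographically by id
  expect_equal(top1_loss(c(1, 1), c(0.2, 0.9), ids = c("b", "a")), 0)
  expect_equal(top1_loss(c(1, 1), c(0.2, 0.9), ids = c("a", "b")), 0.7)
})

test_that("Fisher-z averaging matches the direct formula and stays finite", {
  expect_equal(fisher_z_mean(c(0.8, 0.6)),
               tanh((atanh(0.8) + atanh(0.6)) / 2))
  expect_true(is.finite(fisher_z_mean(c(1, 1))))
  expect_equal(fisher_z_mean(c(1, 1)), 1, tolerance = 1e-9)
})

make_eval_fixture <- function(n_targets = 3, n_decoys = 8, seed = 301,
                              noise = 0.1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_targets), function(t) {
    tm <- runif(n_decoys)
    data.frame(target_id = sprintf("T%02d", t),
               decoy_id = sprintf("d%02d", seq_len(n_decoys)),
               tm = tm, gdt_ts = runif(n_decoys), lddt = runif(n_decoys),
               inf_all = runif(n_decoys), rmsd = 20 * (1 - tm),
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  g <- composite_score(truth$tm, truth$gdt_ts, truth$lddt)
  pred <- data.frame(target_id = truth$target_id, decoy_id = truth$decoy_id,
                     score = g + rnorm(nrow(truth), sd = noise),
                     stringsAsFactors = FALSE)
  list(pred = pred, truth = truth)
}

test_that("a perfect predictor yields unit correlations and zero loss", {
  fx <- make_eval_fixture(noise = 0)
  tab <- eval_table(fx$pred, fx$truth)
  rep <- correlation_report(tab, "G")
  expect_equal(rep$global_r, 1, tolerance = 1e-12)
  expect_equal(rep$global_rho, 1, tolerance = 1e-12)
  expect_equal(rep$per_target_loss, 0)
  expect_equal(rep$per_target_r, 1, tolerance = 1e-12)
  expect_equal(rep$n_targets, 3)
})

test_that("per-target averages combine plain and Fisher-z means correctly", {
  # two targets engineered to have known per-target correlations
  fx <- make_eval_fixture(n_targets = 2, noise = 0.15, seed = 305)
  tab <- eval_table(fx$pred, fx$truth)
  rep <- correlation_report(tab, "G")
  per_r <- rep$per_target$r
  expect_equal(rep$per_target_r, mean(per_r))
  expect_equal(rep$per_target_r_fisher, tanh(mean(atanh(per_r))))
})

test_that("Spearman metrics are invariant under monotone transforms", {
  fx <- make_eval_fixture(noise = 0.2, seed = 311)
  tab <- eval_table(fx$pred, fx$truth)
  r1 <- correlation_report(tab, "G")
  tab2 <- tab
  tab2$predicted <- exp(3 * tab2$predicted) + 1
  r2 <- correlation_report(tab2, "G")
  # within-target ranks are what a monotone transform preserves; the pooled
  # global statistic mixes min-max-normalized values across targets and is
  # only invariant to per-target affine maps (checked below)
  expect_equal(r1$per_target_rho, r2$per_target_rho, tolerance = 1e-12)
  expect_equal(r1$per_target_rho_fisher, r2$per_target_rho_fisher,
               tolerance = 1e-12)
})

test_that("global metrics ignore per-target affine rescaling of predictions", {
  fx <- make_eval_fixture(noise = 0.2, seed = 317)
  tab <- eval_table(fx$pred, fx$truth)
  r1 <- correlation_report(tab, "G")
  tab2 <- tab
  for (tg in unique(tab2$target_id)) {
    ii <- tab2$target_id == tg
    tab2$predicted[ii] <- runif(1, 1, 5) * tab2$predicted[ii] + rnorm(1)
  }
  r2 <- correlation_report(tab2, "G")
  expect_equal(r1$global_r, r2$global_r, tolerance = 1e-12)
  expect_equal(r1$global_rho, r2$global_rho, tolerance = 1e-12)
})

test_that("shuffled predictions have near-zero average rank correlation", {
  fx <- make_eval_fixture(n_targets = 2, n_decoys = 30, noise = 0)
  rhos <- vapply(1:60, function(rep) {
    pred <- fx$pred
    set.seed(400 + rep)
    for (tg in unique(pred$target_id)) {
      ii <- pred$target_id == tg
      pred$score[ii] <- sample(pred$score[ii])
    }
    correlation_report(eval_table(pred, fx$truth), "G")$global_rho
  }, numeric(1))
  se <- sd(rhos) / sqrt(length(rhos))
  expect_lt(abs(mean(rhos)), 2 * se + 0.05)
})

test_that("RMSD ground truth is negated and zero-variance targets dropped", {
  fx <- make_eval_fixture(noise = 0)
  tab <- eval_table(fx$pred, fx$truth)
  rep <- correlation_report(tab, "rmsd")
  # rmsd was constructed as a decreasing function of tm
  expect_gt(rep$global_rho, 0)

  tab$predicted[tab$target_id == "T01"] <- 0.5
  expect_message(rep2 <- correlation_report(tab, "G"), "zero-variance")
  expect_equal(rep2$n_dropped, 1)
  expect_equal(nrow(rep2$per_target), 3)
})

test_that("eval tables validate joins and conventions", {
  fx <- make_eval_fixture()
  bad <- fx$pred
  bad$decoy_id[1] <- "nonexistent"
  expect_error(eval_table(bad, fx$truth), "without ground truth")
  dup <- rbind(fx$pred, fx$pred[1, ])
  expect_error(eval_table(dup, fx$truth), "duplicate")
  # lower-better predictions are negated on ingestion
  tab_lb <- eval_table(transform(fx$pred, score = -score), fx$truth,
                       convention = "lower_better")
  expect_equal(tab_lb$predicted, eval_table(fx$pred, fx$truth)$predicted)
  # G requires all three components
  tr2 <- fx$truth[, c("target_id", "decoy_id", "tm", "gdt_ts")]
  expect_error(correlation_report(eval_table(fx$pred, tr2), "G"), "lddt")
})
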