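# CASP-style assessment harness: composite ground truth, per-target min-max
# normalization, global and per-target Pearson/Spearman correlations (plain
# and Fisher-z averaged), and top-1 loss.

#' Composite ground-truth score
#'
#' The weighted combination of three structural similarity measures used as
#' the assessment aggregate: `G = 0.3*TM + 0.3*GDT_TS + 0.4*lDDT`.
#'
#' @param tm,gdt_ts,lddt Numeric vectors in [0, 1]; no missing values
#'   (no imputation is performed).
#' @return G in [0, 1].
#' @export
composite_score <- function(tm, gdt_ts, lddt) {
  if (anyNA(tm) || anyNA(gdt_ts) || anyNA(lddt)) {
    stop_user("composite score: missing component (tm, gdt_ts and lddt are all required)")
  }
  stopifnot(length(tm) == length(gdt_ts), length(tm) == length(lddt))
  if (any(c(tm, gdt_ts, lddt) < 0) || any(c(tm, gdt_ts, lddt) > 1)) {
    stop_user("composite score components must lie in [0, 1]")
  }
  0.3 * tm + 0.3 * gdt_ts + 0.4 * lddt
}

#' Per-target min-max normalization
#'
#' `(x - min) / (max - min)`, mapping each target's scores to [0, 1] so decoy
#' scores are comparable when pooled across targets. A constant vector maps
#' to all 0.5 (midpoint convention, avoids division by zero).
#'
#' @param scores Numeric vector, length >= 2.
#' @return Normalized vector in [0, 1].
#' @export
minmax_normalize <- function(scores) {
  if (length(scores) < 2) stop_user("min-max normalization needs >= 2 values")
  if (anyNA(scores)) stop_user("min-max normalization: missing values")
  rng <- range(scores)
  if (rng[1] == rng[2]) return(rep(0.5, length(scores)))
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Orient scores so that higher means better
#'
#' Methods reporting energies or RMSD-like fitness (lower is better) are
#' negated so every score obeys the higher-is-better convention downstream.
#'
#' @param scores Numeric vector.
#' @param convention `"higher_better"` (identity) or `"lower_better"` (negate).
#' @return Oriented scores.
#' @export
negate_if_energy <- function(scores,
                             convention = c("higher_better", "lower_better")) {
  convention <- match.arg(convention)
  if (convention == "lower_better") -scores else scores
}

#' Top-1 loss
#'
#' The absolute difference between the ground truth of the decoy ranked first
#' by the predictor and the ground truth of the best decoy. Ties in the
#' predicted score are broken lexicographically by decoy id (reproducible
#' stand-in for "arbitrary").
#'
#' @param predicted,truth Aligned numeric vectors (same decoys, same order).
#' @param ids Optional decoy ids for tie-breaking; defaults to positions.
#' @param normalized Normalize `truth` with [minmax_normalize()] first.
#' @return Loss >= 0.
#' @export
top1_loss <- function(predicted, truth, ids = NULL, normalized = FALSE) {
  if (length(predicted) != length(truth) || length(predicted) < 1) {
    stop_user("top-1 loss: predicted and truth must align and be non-empty")
  }
  ids <- ids %||% sprintf("%06d", seq_along(predicted))
  if (length(ids) != length(predicted)) {
    stop_user("top-1 loss: ids misaligned with scores")
  }
  if (normalized) truth <- minmax_normalize(truth)
  top <- order(-predicted, ids, method = "radix")[1]
  abs(truth[top] - max(truth))
}

#' Fisher-z averaged correlation
#'
#' Averages correlations on the z scale: `tanh(mean(atanh(r)))`, with r
#' clipped to +/- (1 - 1e-12) so perfect correlations stay finite.
#'
#' @param r Vector of correlation coefficients.
#' @return Scalar average in [-1, 1].
#' @export
fisher_z_mean <- function(r) {
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  tanh(mean(atanh(r)))
}

#' Build an evaluation table
#'
#' Joins per-decoy predictions with ground-truth metric columns on
#' `(target_id, decoy_id)`.
#'
#' @param predictions Data frame `target_id, decoy_id, score`.
#' @param truth Data frame `target_id, decoy_id` plus any of `tm, gdt_ts,
#'   lddt, inf_all, rmsd`.
#' @param convention Score orientation of `predictions`, see
#'   [negate_if_energy()].
#' @return An `eval_table` data frame.
#' @export
eval_table <- function(predictions, truth,
                       convention = c("higher_better", "lower_better")) {
  convention <- match.arg(convention)
  need_p <- c("target_id", "decoy_id", "score")
  if (!all(need_p %in% names(predictions))) {
    stop_user("predictions need columns: ", paste(need_p, collapse = ", "))
  }
  if (!all(c("target_id", "decoy_id") %in% names(truth))) {
    stop_user("truth needs columns target_id and decoy_id")
  }
  key_p <- paste(predictions$target_id, predictions$decoy_id, sep = "\r")
  key_t <- paste(truth$target_id, truth$decoy_id, sep = "\r")
  if (anyDuplicated(key_p) || anyDuplicated(key_t)) {
    stop_user("duplicate (target_id, decoy_id) rows")
  }
  unmatched <- setdiff(key_p, key_t)
  if (length(unmatched) > 0) {
    stop_user("predictions without ground truth, e.g.: ",
              paste(gsub("\r", "/", utils::head(unmatched, 5)), collapse = ", "))
  }
  m <- match(key_p, key_t)
  out <- data.frame(target_id = predictions$target_id,
                    decoy_id = predictions$decoy_id,
                    predicted = negate_if_energy(predictions$score, convention),
                    stringsAsFactors = FALSE)
  for (col in intersect(c("tm", "gdt_ts", "lddt", "inf_all", "rmsd"),
                        names(truth))) {
    out[[col]] <- truth[[col]][m]
  }
  class(out) <- c("eval_table", "data.frame")
  out
}

truth_vector <- function(tab, truth_metric) {
  if (truth_metric == "G") {
    for (col in c("tm", "gdt_ts", "lddt")) {
      if (is.null(tab[[col]])) {
        stop_user("composite truth G requires column '", col, "'")
      }
    }
    return(composite_score(tab$tm, tab$gdt_ts, tab$lddt))
  }
  v <- tab[[truth_metric]]
  if (is.null(v)) stop_user("missing ground-truth column '", truth_metric, "'")
  if (truth_metric == "rmsd") v <- negate_if_energy(v, "lower_better")
  v
}

#' Correlation and loss report
#'
#' Computes the standard assessment battery for one predictor against one
#' ground-truth metric: global Pearson r and Spearman rho over all decoys
#' pooled after per-target min-max normalization of both predictions and
#' truth; per-target r and rho averaged across targets both arithmetically
#' and via Fisher's z-transformation; and the mean per-target top-1 loss
#' (computed on the raw, post-orientation ground truth). Targets where either
#' vector is constant are dropped from the correlation averages (their count
#' is reported); RMSD truth is negated so higher is better.
#'
#' @param tab An [eval_table()].
#' @param truth_metric One of `"G"`, `"inf_all"`, `"tm"`, `"gdt_ts"`,
#'   `"lddt"`, `"rmsd"`.
#' @return A `metric_report` list: `global_r`, `global_rho`,
#'   `per_target_r`, `per_target_rho` (arithmetic means),
#'   `per_target_r_fisher`, `per_target_rho_fisher`, `per_target_loss`,
#'   `n_targets`, `n_decoys`, `n_dropped`, and the `per_target` data frame.
#' @export
correlation_report <- function(tab, truth_metric = c("G", "inf_all", "tm",
                                                     "gdt_ts", "lddt",
                                                     "rmsd")) {
  truth_metric <- match.arg(truth_metric)
  truth <- truth_vector(tab, truth_metric)
  if (anyNA(truth) || anyNA(tab$predicted)) {
    stop_user("evaluation table has missing predicted or truth values")
  }
  targets <- split(seq_len(nrow(tab)), tab$target_id)
  if (any(lengths(targets) < 2)) {
    stop_user("every target needs at least 2 decoys")
  }
  per <- lapply(names(targets), function(tg) {
    ii <- targets[[tg]]
    p <- tab$predicted[ii]; y <- truth[ii]
    constant <- stats::sd(p) == 0 || stats::sd(y) == 0
    data.frame(
      target_id = tg,
      n = length(ii),
      r = if (constant) NA_real_ else stats::cor(p, y),
      rho = if (constant) NA_real_ else stats::cor(p, y, method = "spearman"),
      loss = top1_loss(p, y, ids = tab$decoy_id[ii]),
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  n_dropped <- sum(is.na(per$r))
  if (n_dropped > 0) {
    message(n_dropped,
            " zero-variance target(s) dropped from correlation averages")
  }
  # pooled global metrics on per-target min-max normalized scores
  norm_p <- norm_y <- rep(NA_real_, nrow(tab))
  for (ii in targets) {
    norm_p[ii] <- minmax_normalize(tab$predicted[ii])
    norm_y[ii] <- minmax_normalize(truth[ii])
  }
  structure(list(
    truth_metric = truth_metric,
    global_r = stats::cor(norm_p, norm_y),
    global_rho = stats::cor(norm_p, norm_y, method = "spearman"),
    per_target_r = mean(per$r, na.rm = TRUE),
    per_target_rho = mean(per$rho, na.rm = TRUE),
    per_target_r_fisher = fisher_z_mean(per$r[!is.na(per$r)]),
    per_target_rho_fisher = fisher_z_mean(per$rho[!is.na(per$rho)]),
    per_target_loss = mean(per$loss),
    n_targets = length(targets),
    n_decoys = nrow(tab),
    n_dropped = n_dropped,
    per_target = per
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> truth=%s over %d targets / %d decoys\n",
              x$truth_metric, x$n_targets, x$n_decoys))
  cat(sprintf("  global r=%.3f rho=%.3f | per-target r=%.3f rho=%.3f (Fisher-z %.3f/%.3f) | loss=%.3f\n",
              x$global_r, x$global_rho, x$per_target_r, x$per_target_rho,
              x$per_target_r_fisher, x$per_target_rho_fisher,
              x$per_target_loss))
  invisible(x)
}

#' Write a metric report to CSV and JSON
#'
#' @param report A `metric_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- report[c("truth_metric", "global_r", "global_rho", "per_target_r",
                   "per_target_rho", "per_target_r_fisher",
                   "per_target_rho_fisher", "per_target_loss", "n_targets",
                   "n_decoys", "n_dropped")]
  csv_path <- file.path(dir, "report.csv")
  utils::write.csv(as.data.frame(flat), csv_path, row.names = FALSE,
                   quote = FALSE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(c(flat, list(per_target = report$per_target)),
                       json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv_path, json_path))
}
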