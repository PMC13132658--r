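# Independent oracles, written as literal transcriptions of the defining
# formulas (plain loops, no shared code with the package implementation).

# INF by explicit enumeration of TP / FP / FN over the two pair sets.
oracle_inf <- function(map_a, map_b) {
  pa <- map_a$pairs; pb <- map_b$pairs
  if (nrow(pa) == 0 && nrow(pb) == 0) return(1)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(0)
  in_b <- logical(nrow(pa))
  for (r in seq_len(nrow(pa))) {
    for (s in seq_len(nrow(pb))) {
      if (pa$i[r] == pb$i[s] && pa$j[r] == pb$j[s]) in_b[r] <- TRUE
    }
  }
  in_a <- logical(nrow(pb))
  for (s in seq_len(nrow(pb))) {
    for (r in seq_len(nrow(pa))) {
      if (pb$i[s] == pa$i[r] && pb$j[s] == pa$j[r]) in_a[s] <- TRUE
    }
  }
  tp <- sum(in_b)
  fp <- sum(!in_b)
  fn <- sum(!in_a)
  if (tp == 0) return(0)
  sqrt((tp / (tp + fp)) * (tp / (tp + fn)))
}

# Minimum RMSD over rigid transforms by brute force: rotations parametrized
# by unit quaternions on a random grid, best grid point refined numerically.
oracle_min_rmsd <- function(A, B, n_grid = 3000) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  quat_to_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
  }
  rmsd_of <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best_q <- NULL; best <- Inf
  for (g in seq_len(n_grid)) {
    q <- stats::rnorm(4)
    v <- rmsd_of(q)
    if (v < best) { best <- v; best_q <- q }
  }
  fit <- stats::optim(best_q, rmsd_of, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  min(best, fit$value)
}

# TM-score by exhaustive seeding: every contiguous fragment of length >= 4
# over the usable positions seeds a superposition that is refined to
# convergence under the 8 -> 4.5 Angstrom cutoff schedule.
oracle_tm_exhaustive <- function(a, b, params = NULL) {
  params <- params %||% tm_params(a$length)
  Af <- rep_coords(a); Bf <- rep_coords(b)
  ok <- stats::complete.cases(Af) & stats::complete.cases(Bf)
  A <- Af[ok, , drop = FALSE]; B <- Bf[ok, , drop = FALSE]
  n <- nrow(A)
  d0 <- params$d0; L_norm <- params$L_norm
  fit_rotation <- function(P, Q) {
    cp <- colMeans(P); cq <- colMeans(Q)
    H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
    sv <- La.svd(H)
    d <- sign(det(t(sv$vt) %*% t(sv$u)))
    R <- t(sv$vt) %*% diag(c(1, 1, d)) %*% t(sv$u)
    list(R = R, t = cq - R %*% cp)
  }
  schedule <- c(8, 7, 6, 5, 4.5)
  best <- 0
  for (len in 4:n) {
    for (start in 1:(n - len + 1)) {
      sel <- start:(start + len - 1)
      for (iter in 1:100) {
        tr <- fit_rotation(A[sel, , drop = FALSE], B[sel, , drop = FALSE])
        moved <- sweep(A %*% t(tr$R), 2, as.numeric(tr$t), `+`)
        d <- sqrt(rowSums((moved - B)^2))
        sc <- sum(1 / (1 + (d / d0)^2)) / L_norm
        if (sc > best) best <- sc
        cut <- schedule[min(iter, length(schedule))]
        nxt <- which(d < cut)
        while (length(nxt) < 3 && cut < max(d) + 1) {
          cut <- cut + 0.5
          nxt <- which(d < cut)
        }
        if (iter >= length(schedule) && identical(nxt, sel)) break
        sel <- nxt
        if (length(sel) < 3) break
      }
    }
  }
  min(best, 1)
}

# Eqs for the consensus core, as naive double loops.
oracle_consensus_q <- function(Tv, Iv) {
  n <- nrow(Tv)
  M <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) M[i, j] <- Tv[i, j] * Iv[i, j]
  q <- numeric(n)
  for (i in 1:n) {
    terms <- numeric(0)
    for (j in 1:n) if (j != i) terms <- c(terms, M[i, j])
    q[i] <- sum(terms) / (n - 1)
  }
  q
}

# Top-1 loss applied literally to the definition.
oracle_top1 <- function(predicted, truth) {
  top <- which(predicted == max(predicted))[1]
  abs(truth[top] - max(truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
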