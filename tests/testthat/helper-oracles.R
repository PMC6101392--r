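# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Objective of the L1-regularized squared-hinge problem, written directly
# from the definition (no shared code with llsvm_objective()).
oracle_objective <- function(w, X, y, C) {
  n <- nrow(X)
  loss <- 0
  for (i in seq_len(n)) {
    b <- 1 - y[i] * sum(w * X[i, ])
    if (b > 0) loss <- loss + b^2
  }
  sum(abs(w)) + C * loss
}

# Dense grid search over the weight cube, refined around the coarse
# minimum. Sound for locating the global minimum of a convex function:
# the coarse pass brackets the minimizer, the fine passes tighten it.
oracle_grid_min <- function(X, y, C, lim = 3, coarse = 0.05) {
  p <- ncol(X)
  stopifnot(p <= 3)
  eval_grid <- function(lo, hi, step) {
    axes <- lapply(seq_len(p), function(j) seq(lo[j], hi[j], by = step))
    W <- as.matrix(expand.grid(axes))
    scores <- W %*% t(X)                       # nGrid x nSamples
    B <- 1 - sweep(scores, 2, y, "*")
    B[B < 0] <- 0
    obj <- rowSums(abs(W)) + C * rowSums(B^2)
    i <- which.min(obj)
    list(w = W[i, ], obj = obj[i])
  }
  lo <- rep(-lim, p); hi <- rep(lim, p)
  res <- eval_grid(lo, hi, coarse)
  step <- coarse
  for (r in 1:2) {
    lo <- res$w - 2 * step
    hi <- res$w + 2 * step
    step <- step / 10
    res <- eval_grid(lo, hi, step)
  }
  # the oracle value is the exact minimum only when the argmin is interior
  res$interior <- all(abs(res$w) < lim - 2 * coarse)
  res
}

# 1-D grid oracle for the coordinate subproblem
# g(z) = |w_j + z| + d1 z + (d2 / 2) z^2 over z in [-10, 10], step 1e-4.
oracle_subproblem_min <- function(w_j, d1, d2) {
  z <- seq(-10, 10, by = 1e-4)
  g <- abs(w_j + z) + d1 * z + d2 / 2 * z^2
  z[which.min(g)]
}

# Plain transcription of the variable-step schedule: returns the per-
# iteration deletion counts. Written as a count-only simulator, before the
# data-driven implementation.
oracle_schedule <- function(n_total, n_selected, s_initial) {
  temp <- n_total; n <- n_total; s <- s_initial
  counts <- integer(0)
  while (n > n_selected) {
    d <- min(s, n - n_selected)
    n <- n - d
    counts <- c(counts, d)
    while (n <= temp / 2 && s > 1) {
      temp <- n
      s <- s %/% 2
    }
  }
  counts
}

# Classic one-at-a-time RFE, written independently of vssrfe_select():
# returns the surviving original column indices.
oracle_classic_rfe <- function(X, y, n_selected, estimator) {
  surviving <- seq_len(ncol(X))
  while (length(surviving) > n_selected) {
    w <- abs(estimator(X[, surviving, drop = FALSE], y))
    # lowest |w| deleted; ties -> highest original column index goes first
    worst <- which(w == min(w))
    drop_local <- worst[which.max(surviving[worst])]
    surviving <- surviving[-drop_local]
  }
  surviving
}

# Brute-force pairwise AUC.
oracle_auc <- function(scores, truth, positive) {
  pos <- which(truth == positive)
  neg <- which(truth != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Small labeled fixture: perfectly separable along gene 1.
separable_fixture <- function(n_per_class = 10, n_genes = 20, shift = 3,
                              seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * n_genes), n, n_genes)
  cls <- rep(c(-1, 1), each = n_per_class)
  X[, 1] <- X[, 1] * 0.3 + cls * shift
  colnames(X) <- paste0("g", seq_len(n_genes))
  df <- tibble::as_tibble(as.data.frame(X))
  df$label <- ifelse(cls == -1, "a", "b")
  df
}

# Half-away-from-zero rounding (ratio tables print 1.305 as 1.31).
round_half_away_test <- function(x, digits) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

write_tiny_csv <- function(path, header, rows) {
  writeLines(c(header, rows), path)
  path
}
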