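#' Plan a variable-step-size elimination schedule
#'
#' Simulates the step-size bookkeeping of VSSRFE without touching data.
#' Starting from `s_initial`, each iteration deletes
#' `min(current_step, n_remaining - n_selected)` genes; whenever the
#' surviving count has fallen to half (or less) of the reference count at
#' the last halving, the step is halved (integer floor), repeatedly until
#' the condition fails or the step is 1. With `s_initial = 1` this is the
#' classic one-gene-at-a-time RFE schedule.
#'
#' @param n_total starting gene count.
#' @param n_selected target gene count (1 <= n_selected < n_total).
#' @param s_initial initial step size (>= 1).
#' @return Tibble with one row per elimination iteration: `iteration`,
#'   `step_size` (the schedule's step value), `n_deleted` (after clamping),
#'   `n_remaining` (after the deletion).
#' @export
#' @examples
#' elimination_schedule(16, 2, 4)$n_deleted   # 4 4 2 2 1 1
elimination_schedule <- function(n_total, n_selected, s_initial) {
  n_total <- as.integer(n_total)
  n_selected <- as.integer(n_selected)
  s_initial <- as.integer(s_initial)
  if (n_selected < 1 || n_selected >= n_total) {
    abort("Need 1 <= n_selected < n_total.")
  }
  if (s_initial < 1) abort("`s_initial` must be >= 1.")
  temp <- n_total
  n <- n_total
  s <- s_initial
  it <- 0L
  rows <- list()
  while (n > n_selected) {
    it <- it + 1L
    d <- min(s, n - n_selected)
    n <- n - d
    rows[[it]] <- c(iteration = it, step_size = s, n_deleted = d,
                    n_remaining = n)
    while (n <= temp / 2 && s > 1) {
      temp <- n
      s <- s %/% 2L
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' LLSVM estimator for recursive feature elimination
#'
#' Returns a weight-producing estimator closure satisfying the elimination
#' contract: a function of `(X, y)` returning one finite weight per column.
#'
#' @param C penalty factor passed to [llsvm_fit_matrix()].
#' @param ... further arguments to [llsvm_fit_matrix()].
#' @return A function `(X, y) -> numeric weights`.
#' @export
llsvm_estimator <- function(C = 1, ...) {
  function(X, y) {
    unname(llsvm_fit_matrix(X, y, C = C, ...)$weights)
  }
}

#' Linear-SVM estimator adapter (e1071)
#'
#' Wraps a standard linear support vector machine as an elimination
#' estimator; the weight vector is recovered from the support-vector
#' coefficients as w = t(coefs) %*% SV. Requires the e1071 package.
#'
#' @param cost SVM cost parameter.
#' @return A function `(X, y) -> numeric weights`.
#' @export
svm_estimator <- function(cost = 1) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    abort("The e1071 package is required for `svm_estimator()`.")
  }
  function(X, y) {
    fit <- e1071::svm(X, factor(y), kernel = "linear", cost = cost,
                      scale = FALSE)
    drop(t(fit$coefs) %*% fit$SV)
  }
}

#' Recursive feature elimination with variable step size
#'
#' Backward gene selection: train a weight-producing estimator on the
#' surviving genes, rank them by |weight| (descending), delete the lowest-
#' ranked genes according to the [elimination_schedule()], and repeat until
#' `n_selected` genes remain. The step starts at `s_initial` and halves as
#' the surviving set halves, so early iterations discard many clearly
#' irrelevant genes cheaply while the final eliminations proceed one gene
#' at a time — the premise being that the later a gene is deleted, the more
#' informative it is.
#'
#' Ties in |weight| (common with the sparse LLSVM estimator, which produces
#' many exact zeros) are broken by original column position: the stable sort
#' keeps earlier columns ranked higher, so later columns are deleted first.
#'
#' @param df expression tibble with a two-class label column.
#' @param label_col label column name.
#' @param n_selected number of genes to keep.
#' @param s_initial initial step size; 1 gives classic RFE.
#' @param estimator weight-producing function `(X, y) -> numeric`, e.g.
#'   [llsvm_estimator()] (default) or [svm_estimator()].
#' @param seed optional seed set once before the loop (for stochastic
#'   estimators; the bundled estimators are deterministic).
#' @return An object of class `vssrfe_trace`: `tidy()` gives the full gene
#'   ranking (rank 1 = most important; survivors ranked by final |weight|,
#'   eliminated genes by reverse elimination order, within a batch by
#'   |weight|), `glance()` the iteration/fit counts, `autoplot()` the
#'   elimination trajectory. `$selected` holds the final gene ids.
#' @export
#' @examples
#' sim <- simulate_expression(15, 15, 60, n_informative = 4, effect = 3,
#'                            seed = 7)
#' tr <- vssrfe_select(sim$data, n_selected = 4, s_initial = 16)
#' tr$selected
vssrfe_select <- function(df, label_col = "label", n_selected,
                          s_initial = 1, estimator = llsvm_estimator(),
                          seed = NULL) {
  dec <- decompose_expression(df, label_col)
  if (!is.null(seed)) set.seed(seed)
  X <- dec$X
  y <- dec$y
  gene_ids <- dec$gene_ids
  n_total <- length(gene_ids)
  n_selected <- as.integer(n_selected)
  s_initial <- as.integer(s_initial)
  if (n_selected < 1 || n_selected >= n_total) {
    abort("Need 1 <= n_selected < total gene count.")
  }
  if (s_initial < 1) abort("`s_initial` must be >= 1.")

  surviving <- seq_len(n_total)     # original column indices
  temp <- n_total
  s <- s_initial
  it <- 0L
  iter_rows <- list()
  eliminated <- list()              # per-iteration original indices, best-first
  w_final <- NULL

  while (length(surviving) > n_selected) {
    it <- it + 1L
    w <- estimator(X[, surviving, drop = FALSE], y)
    if (length(w) != length(surviving) || !all(is.finite(w))) {
      abort(sprintf(
        "Estimator returned invalid weights at iteration %d (need %d finite values).",
        it, length(surviving)))
    }
    d <- min(s, length(surviving) - n_selected)
    # rank surviving genes by |w| descending; ties keep earlier original
    # column first, so the later column is deleted first
    ord <- order(-abs(w), surviving)
    drop_pos <- ord[(length(surviving) - d + 1L):length(surviving)]
    # within the batch, larger |w| = more important (ranked better later)
    eliminated[[it]] <- surviving[drop_pos]
    iter_rows[[it]] <- c(iteration = it, step_size = s, n_deleted = d,
                         n_remaining = length(surviving) - d)
    keep_pos <- sort(setdiff(seq_along(surviving), drop_pos))
    w_final <- w[keep_pos]
    surviving <- surviving[keep_pos]
    while (length(surviving) <= temp / 2 && s > 1) {
      temp <- length(surviving)
      s <- s %/% 2L
    }
  }

  # ranking: survivors first (by final |weight| desc, ties by column), then
  # eliminated batches in reverse elimination order (later = better)
  if (is.null(w_final)) w_final <- rep(0, length(surviving))
  surv_order <- surviving[order(-abs(w_final), surviving)]
  elim_order <- rev(eliminated)            # last-deleted batch first
  ranked_idx <- c(surv_order, unlist(elim_order))
  ranking <- tibble::tibble(
    gene_id = gene_ids[ranked_idx],
    rank = seq_len(n_total),
    elimination_iteration = c(
      rep(NA_integer_, length(surv_order)),
      unlist(lapply(rev(seq_len(it)), function(i) {
        rep(i, length(eliminated[[i]]))
      }))
    )
  )

  structure(
    list(
      ranking = ranking,
      selected = gene_ids[sort(surviving)],
      final_weights = stats::setNames(w_final, gene_ids[surviving]),
      iterations = tibble::as_tibble(do.call(rbind, iter_rows)),
      n_total = n_total,
      n_selected = n_selected,
      s_initial = s_initial,
      n_fits = it
    ),
    class = "vssrfe_trace"
  )
}

#' Classic SVM-RFE (step size 1)
#'
#' One-gene-per-iteration recursive feature elimination: exactly
#' [vssrfe_select()] with `s_initial = 1`.
#'
#' @inheritParams vssrfe_select
#' @return A `vssrfe_trace`.
#' @export
rfe_select <- function(df, label_col = "label", n_selected,
                       estimator = llsvm_estimator(), seed = NULL) {
  vssrfe_select(df, label_col = label_col, n_selected = n_selected,
                s_initial = 1, estimator = estimator, seed = seed)
}

#' @export
tidy.vssrfe_trace <- function(x, ...) x$ranking

#' @export
glance.vssrfe_trace <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total,
    n_selected = x$n_selected,
    s_initial = x$s_initial,
    n_iterations = x$n_fits,
    n_fits = x$n_fits
  )
}

#' @export
print.vssrfe_trace <- function(x, ...) {
  cat(sprintf(
    "<vssrfe_trace> %d -> %d genes in %d iterations (s_initial = %d)\n",
    x$n_total, x$n_selected, x$n_fits, x$s_initial))
  cat("selected:", paste(utils::head(x$selected, 10), collapse = ", "),
      if (length(x$selected) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
autoplot.vssrfe_trace <- function(object, ...) {
  df <- object$iterations
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$n_remaining)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(ggplot2::aes(size = .data$step_size), alpha = 0.6) +
    ggplot2::scale_size_continuous(name = "step size") +
    ggplot2::labs(x = "Elimination iteration", y = "Surviving genes",
                  title = "VSSRFE elimination trajectory") +
    ggplot2::theme_minimal()
}
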