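#' L1-regularized squared-hinge objective
#'
#' Evaluates ||w||_1 + C * sum over the active set of b_i(w)^2, where
#' b_i(w) = 1 - y_i w'x_i and the active set is {i : b_i(w) > 0} (strict
#' inequality). This is the training objective of the LLSVM solver; the L1
#' term drives unimportant gene weights exactly to zero.
#'
#' @param w numeric weight vector, one entry per gene.
#' @param X numeric matrix, samples by genes.
#' @param y labels in {-1, +1}.
#' @param C penalty factor (> 0) weighting the squared-hinge loss.
#' @return The objective value (scalar).
#' @export
llsvm_objective <- function(w, X, y, C) {
  X <- as.matrix(X)
  if (length(w) != ncol(X)) abort("length(w) must equal ncol(X).")
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X).")
  b <- 1 - y * drop(X %*% w)
  sum(abs(w)) + C * sum(b[b > 0]^2)
}

#' First and second derivatives of the coordinate subproblem
#'
#' For coordinate `j`, returns the derivative pair of the smooth loss part
#' at step 0: `d1 = -2C * sum_{i in I(w)} y_i x_{ij} b_i(w)` and
#' `d2 = max(2C * sum_{i in I(w)} x_{ij}^2, hessian_floor)`, sums running
#' over the active set only. The floor keeps the Newton step defined when
#' the active set is empty.
#'
#' @param j coordinate (gene) index, 1-based.
#' @inheritParams llsvm_objective
#' @param hessian_floor lower bound on `d2` (default 1e-12).
#' @return Named numeric vector `c(d1, d2)`.
#' @export
llsvm_derivatives <- function(j, w, X, y, C, hessian_floor = 1e-12) {
  X <- as.matrix(X)
  if (length(w) != ncol(X)) abort("length(w) must equal ncol(X).")
  b <- 1 - y * drop(X %*% w)
  act <- b > 0
  d1 <- -2 * C * sum(y[act] * X[act, j] * b[act])
  d2 <- max(2 * C * sum(X[act, j]^2), hessian_floor)
  c(d1 = d1, d2 = d2)
}

#' Closed-form minimizer of the one-variable subproblem
#'
#' Minimizes |w_j + z| + d1*z + (d2/2)*z^2 exactly via subdifferential
#' optimality: the soft-threshold-style three-case solution. When neither
#' one-sided condition holds the coordinate snaps to zero (z* = -w_j),
#' which is how the L1 penalty produces exact sparsity.
#'
#' @param w_j current coordinate value.
#' @param d1,d2 derivative pair from [llsvm_derivatives()]; `d2 > 0`.
#' @return The minimizing step `z*`.
#' @export
#' @examples
#' solve_subproblem(0, -3, 2)    # 1: unconstrained Newton step past the kink
#' solve_subproblem(0.5, 0.2, 1) # -0.5: coordinate snaps to zero
solve_subproblem <- function(w_j, d1, d2) {
  if (d2 <= 0) abort("`d2` must be positive.")
  if (d1 + 1 <= d2 * w_j) {
    -(d1 + 1) / d2
  } else if (d1 - 1 >= d2 * w_j) {
    -(d1 - 1) / d2
  } else {
    -w_j
  }
}

#' Fit an L1-regularized squared-hinge linear SVM by coordinate descent
#'
#' Trains the sparse linear classifier min_w ||w||_1 + C * sum max(0, 1 -
#' y_i w'x_i)^2 by cyclic coordinate descent: coordinates are visited in
#' fixed ascending order, each takes the closed-form Newton-like step of
#' [solve_subproblem()], safeguarded by Armijo backtracking on the true
#' objective so the per-sweep objective trace never increases. There is no
#' intercept: the decision rule is sign(w . x), matching the bias-free
#' formulation (an augmented constant gene can be added by the caller).
#'
#' @param df expression tibble with a two-class label column (classes are
#'   mapped minority -> -1, majority -> +1).
#' @param label_col label column name.
#' @param C penalty factor (> 0). Larger C weights the loss more; as C -> 0
#'   every weight is penalized to exactly 0.
#' @param max_sweeps maximum full passes over the coordinates.
#' @param tol convergence threshold: stop when the largest accepted step in
#'   a sweep is below `tol`.
#' @param w0 optional warm-start weight vector (used by the elimination
#'   loop); defaults to zero.
#' @param linesearch_beta,linesearch_sigma Armijo backtracking parameters in
#'   (0, 1).
#' @param hessian_floor lower bound on the per-coordinate second derivative.
#' @return An object of class `llsvm`: use `tidy()` for per-gene weights,
#'   `glance()` for fit-level summaries, `predict()` for classes or decision
#'   scores, `autoplot()` for the objective trace.
#' @export
#' @examples
#' sim <- simulate_expression(10, 10, 30, n_informative = 5, effect = 3,
#'                            seed = 1)
#' fit <- llsvm(sim$data, C = 1)
#' glance(fit)
llsvm <- function(df, label_col = "label", C = 1, max_sweeps = 1000,
                  tol = 1e-6, w0 = NULL, linesearch_beta = 0.5,
                  linesearch_sigma = 0.01, hessian_floor = 1e-12) {
  dec <- decompose_expression(df, label_col)
  fit <- llsvm_fit_matrix(dec$X, dec$y, C = C, max_sweeps = max_sweeps,
                          tol = tol, w0 = w0,
                          linesearch_beta = linesearch_beta,
                          linesearch_sigma = linesearch_sigma,
                          hessian_floor = hessian_floor)
  fit$gene_ids <- dec$gene_ids
  fit$label_map <- c(`-1` = dec$minority, `1` = dec$majority)
  fit$label_col <- label_col
  fit
}

#' Matrix-interface LLSVM fit
#'
#' Lower-level entry point used by the elimination loop and by estimator
#' adapters: takes the design matrix and the +/-1 labels directly.
#'
#' @inheritParams llsvm
#' @param X numeric matrix, samples by genes.
#' @param y labels in {-1, +1}; both classes must be present.
#' @return An `llsvm` object (without label metadata).
#' @export
llsvm_fit_matrix <- function(X, y, C = 1, max_sweeps = 1000, tol = 1e-6,
                             w0 = NULL, linesearch_beta = 0.5,
                             linesearch_sigma = 0.01, hessian_floor = 1e-12) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) abort("`y` must contain only -1 and +1.")
  if (length(unique(y)) < 2) abort("Training needs both classes present.")
  if (!all(is.finite(X))) abort("Non-finite values in the training matrix.")
  if (C <= 0) abort("`C` must be positive.")
  if (is.null(w0)) w0 <- rep(0, ncol(X))
  if (length(w0) != ncol(X)) abort("`w0` length must equal ncol(X).")
  res <- .llsvm_cd_fit(X, y, C, as.integer(max_sweeps), tol,
                       linesearch_beta, linesearch_sigma, hessian_floor, w0)
  structure(
    list(
      weights = stats::setNames(res$weights, colnames(X)),
      penalty = C,
      n_sweeps_run = res$n_sweeps_run,
      objective_trace = res$objective_trace,
      converged = res$converged,
      tol = tol,
      gene_ids = colnames(X) %||% paste0("g", seq_len(ncol(X)))
    ),
    class = "llsvm"
  )
}

#' Decision scores of a fitted LLSVM
#'
#' @param model an `llsvm` fit.
#' @param newdata expression tibble or numeric matrix with the model's
#'   genes.
#' @param label_col label column name to drop if present.
#' @return Numeric vector of w . x scores (used for AUC).
#' @export
decision_score <- function(model, newdata, label_col = "label") {
  stopifnot(inherits(model, "llsvm"))
  if (is.data.frame(newdata)) {
    keep <- setdiff(names(newdata), c(label_col, ".sample_id"))
    newdata <- as.matrix(newdata[keep])
  }
  X <- as.matrix(newdata)
  if (ncol(X) != length(model$weights)) {
    abort("`newdata` gene count does not match the fitted model.")
  }
  if (!is.null(colnames(X)) && !is.null(model$gene_ids) &&
      !identical(colnames(X), model$gene_ids)) {
    X <- X[, model$gene_ids, drop = FALSE]
  }
  drop(X %*% unname(model$weights))
}

#' Predict classes with a fitted LLSVM
#'
#' The decision rule is sign(w . x); a score of exactly zero maps to the +1
#' (majority) side, a fixed convention that only affects measure-zero ties.
#'
#' @param object an `llsvm` fit.
#' @param newdata expression tibble or numeric matrix.
#' @param type `"class"` for -1/+1 (or original codes when known),
#'   `"score"` for raw decision values.
#' @param ... unused.
#' @return Vector of predictions.
#' @export
predict.llsvm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- decision_score(object, newdata)
  if (type == "score") return(s)
  cls <- ifelse(s >= 0, 1, -1)
  if (!is.null(object$label_map)) {
    unname(object$label_map[as.character(cls)])
  } else {
    cls
  }
}

#' @export
tidy.llsvm <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_ids,
    weight = unname(x$weights),
    abs_weight = abs(unname(x$weights))
  )
}

#' @export
glance.llsvm <- function(x, ...) {
  tibble::tibble(
    penalty = x$penalty,
    objective = x$objective_trace[length(x$objective_trace)],
    n_sweeps_run = x$n_sweeps_run,
    converged = x$converged,
    n_genes = length(x$weights),
    n_nonzero = sum(x$weights != 0)
  )
}

#' @export
print.llsvm <- function(x, ...) {
  cat(sprintf(
    "<llsvm> C = %g, %d genes (%d nonzero), objective %.6g, %d sweeps%s\n",
    x$penalty, length(x$weights), sum(x$weights != 0),
    x$objective_trace[length(x$objective_trace)], x$n_sweeps_run,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
autoplot.llsvm <- function(object, ...) {
  df <- tibble::tibble(
    sweep = seq_along(object$objective_trace) - 1,
    objective = object$objective_trace
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Sweep", y = "Objective",
                  title = "LLSVM coordinate-descent objective trace") +
    ggplot2::theme_minimal()
}
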