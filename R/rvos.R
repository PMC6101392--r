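#' Generate synthetic minority samples by random value-based oversampling
#'
#' RVOS builds each new sample by drawing, independently for every gene, one
#' observed value from that gene's column in the minority-class matrix
#' (uniformly, with replacement). Every synthetic value is therefore a real
#' measured expression value — never an arithmetic interpolation as in
#' SMOTE — which preserves the biological meaning of each entry under the
#' assumption that same-class samples share a distribution.
#'
#' @param minority numeric matrix or data frame of minority-class samples
#'   (rows) by genes (columns); no label column.
#' @param k number of new samples (>= 0).
#' @param seed optional integer seed; the generator is consumed column-major
#'   within each new sample, so results are reproducible.
#' @return A `k` x `ncol(minority)` matrix of synthetic samples.
#' @export
#' @examples
#' m <- rbind(c(1, 10), c(2, 20), c(3, 30))
#' rvos_generate(m, k = 2, seed = 1)
rvos_generate <- function(minority, k, seed = NULL) {
  X <- as.matrix(minority)
  if (!is.numeric(X)) abort("`minority` must be numeric.")
  if (nrow(X) < 1) abort("RVOS needs at least one minority sample.")
  if (k < 0) abort("`k` must be >= 0.")
  k <- as.integer(k)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0, k, ncol(X))
  if (!is.null(colnames(X))) colnames(out) <- colnames(X)
  if (k == 0) return(out)
  # one index draw per (new sample, gene), sample-major order
  idx <- matrix(sample.int(nrow(X), k * ncol(X), replace = TRUE),
                nrow = k, byrow = TRUE)
  for (j in seq_len(ncol(X))) out[, j] <- X[idx[, j], j]
  out
}

#' Balance a two-class expression dataset with RVOS
#'
#' Appends `k = n_majority - n_minority` synthetic minority samples drawn by
#' [rvos_generate()], so the output has equal class counts (imbalance ratio
#' exactly 1). Original rows are preserved verbatim and come first; synthetic
#' rows carry the minority label and `.sample_id`s suffixed `".syn<i>"`.
#'
#' @param df expression tibble with a two-class label column.
#' @param label_col label column name.
#' @param seed integer seed for the value draws.
#' @return Balanced expression tibble.
#' @export
#' @examples
#' df <- simulate_expression(5, 9, 20, seed = 3)$data
#' dataset_summary(rvos_balance(df, seed = 1))$ir   # 1
rvos_balance <- function(df, label_col = "label", seed = NULL) {
  dec <- decompose_expression(df, label_col)
  n_min <- sum(dec$y == -1)
  n_maj <- sum(dec$y == 1)
  k <- n_maj - n_min
  if (k == 0) {
    return(recompose_expression(dec$X, dec$labels_raw, dec$sample_ids,
                                label_col))
  }
  minority_rows <- which(dec$y == -1)
  synth <- rvos_generate(dec$X[minority_rows, , drop = FALSE], k, seed = seed)
  X <- rbind(dec$X, synth)
  labels <- c(dec$labels_raw, rep(dec$minority, k))
  ids <- c(dec$sample_ids,
           paste0(dec$minority, ".syn", seq_len(k)))
  recompose_expression(X, labels, ids, label_col)
}
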