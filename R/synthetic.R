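#' Simulate a microarray-like two-class expression dataset
#'
#' Generates the data structure the selection methods assume: few samples,
#' many genes, a small planted informative subset, and controllable class
#' imbalance. Noise genes are Normal(0, noise_sd^2) in both classes;
#' informative genes are shifted between classes by `effect` (class 1 mean
#' -effect/2, class 2 mean +effect/2), so with effect >= 2 and unit noise
#' the classes are linearly separable in the overparameterized regime
#' typical of expression data. The ground truth is returned separately from
#' the matrix so selection code cannot peek at it.
#'
#' @param n_class1,n_class2 sample counts for the two classes (class 1 is
#'   labelled `"class1"` etc.; when counts differ, the smaller class is the
#'   minority).
#' @param n_genes total gene count.
#' @param n_informative number of planted informative genes (ignored when
#'   `informative_ids` is given).
#' @param effect between-class mean shift on informative genes, in the same
#'   units as the noise.
#' @param noise_sd within-class standard deviation (> 0).
#' @param informative_ids optional integer indices of the informative genes
#'   (defaults to the first `n_informative`).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return List with `data` (expression tibble: genes `g1..g<n>`, `label`,
#'   `.sample_id`) and `informative` (character ids of the planted genes).
#' @export
#' @examples
#' sim <- simulate_expression(22, 40, 2000, seed = 1)
#' dataset_summary(sim$data)
simulate_expression <- function(n_class1, n_class2, n_genes,
                                n_informative = 10, effect = 2,
                                noise_sd = 1, informative_ids = NULL,
                                seed = NULL) {
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  if (effect < 0) abort("`effect` must be >= 0.")
  if (is.null(informative_ids)) {
    if (n_informative > n_genes) abort("More informative genes than genes.")
    informative_ids <- seq_len(n_informative)
  }
  if (length(informative_ids) > 0 &&
      (min(informative_ids) < 1 || max(informative_ids) > n_genes)) {
    abort("`informative_ids` out of range.")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_class1 + n_class2
  X <- matrix(rnorm(n * n_genes, sd = noise_sd), n, n_genes)
  cls <- rep(c(-1, 1), c(n_class1, n_class2))
  for (j in informative_ids) {
    X[, j] <- X[, j] + cls * effect / 2
  }
  colnames(X) <- paste0("g", seq_len(n_genes))
  labels <- rep(c("class1", "class2"), c(n_class1, n_class2))
  list(
    data = recompose_expression(X, labels, paste0("s", seq_len(n)), "label"),
    informative = paste0("g", sort(informative_ids))
  )
}

#' Benchmark-shaped simulation specs
#'
#' The six canonical two-class microarray benchmark shapes (class counts and
#' gene counts) used throughout this field: Colon, CNS, Leukemia, Ovarian,
#' Prostate and Breast. Feeding a row to [simulate_expression()] yields a
#' synthetic dataset with the same sample-to-dimension ratio and imbalance
#' ratio as the named benchmark.
#'
#' @return Tibble with `dataset`, `n_class1`, `n_class2`, `n_genes`.
#' @export
#' @examples
#' shapes <- benchmark_shapes()
#' sim <- simulate_expression(shapes$n_class1[1], shapes$n_class2[1],
#'                            shapes$n_genes[1], seed = 1)
#' dataset_summary(sim$data)   # Colon shape: SDR 3.1%, IR 1.82
benchmark_shapes <- function() {
  tibble::tibble(
    dataset = c("Colon", "CNS", "Leukemia", "Ovarian", "Prostate", "Breast"),
    n_class1 = c(22L, 21L, 25L, 91L, 59L, 46L),
    n_class2 = c(40L, 39L, 47L, 162L, 77L, 51L),
    n_genes = c(2000L, 7129L, 7129L, 15154L, 12600L, 24481L)
  )
}
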