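#' Fit a per-gene standardizer
#'
#' Learns per-gene location/scale so each gene can be centred to zero mean
#' and scaled to unit variance. The scale is the population standard
#' deviation (divide by n) by default, the convention of the usual
#' machine-learning scalers; set `ddof = 1` for the sample version.
#'
#' @param df expression tibble (genes + label column).
#' @param label_col label column name (excluded from standardization).
#' @param ddof delta degrees of freedom: 0 (population, default) or 1
#'   (sample).
#' @return A `standardizer` object; `tidy()` it for a per-gene tibble of
#'   `gene_id`, `mu`, `sigma`.
#' @seealso [apply_standardizer()], [discretize_expression()]
#' @export
fit_standardizer <- function(df, label_col = "label", ddof = 0) {
  stopifnot(ddof %in% c(0, 1))
  dec <- decompose_expression(df, label_col, require_two_classes = FALSE)
  n <- nrow(dec$X)
  if (n < 2) abort("Standardization needs at least 2 samples.")
  mu <- colMeans(dec$X)
  centered <- sweep(dec$X, 2, mu)
  sigma <- sqrt(colSums(centered^2) / (n - ddof))
  structure(
    list(gene_ids = dec$gene_ids, mu = mu, sigma = sigma, ddof = ddof, n = n),
    class = "standardizer"
  )
}

#' @export
tidy.standardizer <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_ids, mu = unname(x$mu),
                 sigma = unname(x$sigma))
}

#' @export
print.standardizer <- function(x, ...) {
  cat(sprintf("<standardizer> %d genes fitted on %d samples (ddof = %d)\n",
              length(x$gene_ids), x$n, x$ddof))
  invisible(x)
}

#' Apply a fitted standardizer
#'
#' Replaces each gene column x by (x - mu) / sigma using the parameters
#' fitted (typically on training data only, to keep train/test separation).
#' Constant genes (sigma = 0) map to all zeros rather than erroring:
#' a constant gene carries no class information and should not crash a
#' pipeline.
#'
#' @param df expression tibble with the same genes the standardizer was
#'   fitted on.
#' @param params a `standardizer` from [fit_standardizer()].
#' @param label_col label column name.
#' @return Standardized expression tibble (labels untouched).
#' @export
apply_standardizer <- function(df, params, label_col = "label") {
  stopifnot(inherits(params, "standardizer"))
  dec <- decompose_expression(df, label_col, require_two_classes = FALSE)
  if (!identical(dec$gene_ids, params$gene_ids)) {
    abort("Gene set of `df` does not match the fitted standardizer.")
  }
  sigma <- params$sigma
  safe <- ifelse(sigma > 0, sigma, 1)
  Z <- sweep(sweep(dec$X, 2, params$mu), 2, safe, "/")
  Z[, sigma == 0] <- 0
  recompose_expression(Z, dec$labels_raw, dec$sample_ids, label_col)
}

#' Three-level discretization of expression values
#'
#' Maps each value to over- (+2), under- (-2) or normal (0) expression
#' relative to the gene's fitted mean and standard deviation:
#' +2 if x > mu + sigma/2, -2 if x < mu - sigma/2, 0 otherwise (strict
#' inequalities; boundary values map to 0). Mutual-information selectors
#' such as mRMR require this discrete form.
#'
#' @param df expression tibble.
#' @param params optional `standardizer`; when `NULL`, thresholds are fitted
#'   on `df` itself. The conventional pipeline discretizes the standardized
#'   matrix, i.e. thresholds at +/- 1/2 around 0.
#' @param label_col label column name.
#' @return Expression tibble whose gene values are in {-2, 0, +2}.
#' @export
discretize_expression <- function(df, params = NULL, label_col = "label") {
  if (is.null(params)) params <- fit_standardizer(df, label_col)
  stopifnot(inherits(params, "standardizer"))
  dec <- decompose_expression(df, label_col, require_two_classes = FALSE)
  if (!identical(dec$gene_ids, params$gene_ids)) {
    abort("Gene set of `df` does not match the fitted standardizer.")
  }
  hi <- matrix(params$mu + params$sigma / 2, nrow(dec$X), ncol(dec$X),
               byrow = TRUE)
  lo <- matrix(params$mu - params$sigma / 2, nrow(dec$X), ncol(dec$X),
               byrow = TRUE)
  D <- matrix(0, nrow(dec$X), ncol(dec$X), dimnames = dimnames(dec$X))
  D[dec$X > hi] <- 2
  D[dec$X < lo] <- -2
  recompose_expression(D, dec$labels_raw, dec$sample_ids, label_col)
}
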