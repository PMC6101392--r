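#' Validate and decompose a labeled expression data frame
#'
#' Internal workhorse behind every verb in the package. An expression data
#' frame holds one sample per row, one gene per (numeric) column, a label
#' column with exactly two distinct class codes, and optionally a
#' `.sample_id` character column. Returns the numeric matrix, the labels
#' mapped to -1/+1 (minority class -1, majority +1; ties broken by
#' lexicographic class code), and the bookkeeping needed to rebuild a tibble.
#'
#' @param df data frame of samples by genes plus a label column.
#' @param label_col name of the label column.
#' @param require_two_classes labels must have exactly two levels (training
#'   and balancing need this; plain summaries do too).
#' @noRd
decompose_expression <- function(df, label_col = "label",
                                 require_two_classes = TRUE) {
  if (!is.data.frame(df)) {
    abort("`df` must be a data frame of samples (rows) by genes (columns).")
  }
  if (!label_col %in% names(df)) {
    abort(sprintf("Label column '%s' not found in `df`.", label_col))
  }
  sample_ids <- if (".sample_id" %in% names(df)) {
    as.character(df[[".sample_id"]])
  } else {
    paste0("s", seq_len(nrow(df)))
  }
  gene_cols <- setdiff(names(df), c(label_col, ".sample_id"))
  if (anyDuplicated(gene_cols)) {
    dup <- unique(gene_cols[duplicated(gene_cols)])
    abort(sprintf("Duplicate gene identifiers: %s.",
                  paste(dup, collapse = ", ")))
  }
  for (g in gene_cols) {
    if (!is.numeric(df[[g]])) {
      abort(sprintf("Gene column '%s' is not numeric.", g))
    }
  }
  X <- as.matrix(df[gene_cols])
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    abort(sprintf("Missing value in gene '%s', sample '%s'.",
                  gene_cols[bad[["col"]]], sample_ids[bad[["row"]]]))
  }
  labels_raw <- as.character(df[[label_col]])
  if (anyNA(labels_raw)) abort("Missing values in the label column.")
  codes <- sort(unique(labels_raw))
  if (require_two_classes && length(codes) != 2) {
    abort(sprintf("Expected exactly 2 classes, found %d (%s).",
                  length(codes), paste(codes, collapse = ", ")))
  }
  y <- NULL
  minority <- majority <- NA_character_
  if (length(codes) == 2) {
    counts <- table(factor(labels_raw, levels = codes))
    # minority -> -1, majority -> +1; tie -> lexicographically first is -1
    minority <- if (counts[[1]] <= counts[[2]]) codes[1] else codes[2]
    majority <- setdiff(codes, minority)
    y <- ifelse(labels_raw == minority, -1, 1)
  }
  list(
    X = X, y = y, labels_raw = labels_raw,
    gene_ids = gene_cols, sample_ids = sample_ids,
    label_col = label_col, minority = minority, majority = majority
  )
}

# Rebuild the tibble form from a decomposition (possibly with new rows).
recompose_expression <- function(X, labels_raw, sample_ids, label_col) {
  out <- tibble::as_tibble(as.data.frame(X, optional = TRUE))
  out[[label_col]] <- labels_raw
  out[[".sample_id"]] <- sample_ids
  out
}

#' Read a labeled expression matrix from delimited text or dense ARFF
#'
#' Reads a samples-by-genes table with one label column. Delimited input
#' (CSV or TSV, auto-detected from the header line) must have a header row,
#' numeric expression cells and exactly two distinct class codes. ARFF input
#' must be the dense dialect with numeric attributes and one nominal class
#' attribute; sparse ARFF is rejected. MATLAB `.mat` containers are not read
#' directly; export them to CSV (e.g. `writetable` in MATLAB or
#' `scipy.io.loadmat` + `pandas.DataFrame.to_csv` in Python) first.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"delimited"` or `"arff"`.
#' @param label_col name or 1-based index of the label column. For ARFF the
#'   default is the nominal attribute (usually `class`).
#' @return A tibble with one numeric column per gene, the label column
#'   (original class codes preserved as character), and a `.sample_id`
#'   column.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("g1,g2,label", "1,10,a", "2,20,a", "3,30,b"), tf)
#' read_expression(tf)
read_expression <- function(path, format = c("auto", "delimited", "arff"),
                            label_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "arff") "arff" else "delimited"
    if (ext == "mat") {
      abort(paste("MATLAB .mat input is not supported; convert to CSV",
                  "(see ?read_expression) and reload."))
    }
  }
  if (format == "arff") {
    first_data <- grep("^\\s*\\{", readLines(path, warn = FALSE), value = TRUE)
    if (length(first_data) > 0) {
      abort("Sparse ARFF is not supported; convert to dense ARFF or CSV.")
    }
    raw <- foreign::read.arff(path)
    if (is.null(label_col)) {
      nominal <- names(raw)[vapply(raw, is.factor, logical(1))]
      if (length(nominal) != 1) {
        abort(sprintf(
          "Expected exactly one nominal (class) attribute, found %d; pass `label_col`.",
          length(nominal)))
      }
      label_col <- nominal
    }
  } else {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = NA)
    if (is.null(label_col)) label_col <- "label"
  }
  if (is.numeric(label_col)) label_col <- names(raw)[label_col]
  if (!label_col %in% names(raw)) {
    abort(sprintf("Label column '%s' not present in %s.", label_col, path))
  }
  gene_cols <- setdiff(names(raw), c(label_col, ".sample_id"))
  for (g in gene_cols) {
    if (!is.numeric(raw[[g]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[g]]))))[1]
      abort(sprintf("Non-numeric expression value in column '%s', row %s of %s.",
                    g, bad %||% "?", basename(path)))
    }
  }
  raw[[label_col]] <- as.character(raw[[label_col]])
  out <- tibble::as_tibble(raw)
  names(out)[names(out) == label_col] <- "label"
  dec <- decompose_expression(out, "label")   # validates invariants
  recompose_expression(dec$X, dec$labels_raw, dec$sample_ids, "label")
}

#' Write a labeled expression tibble to delimited text
#'
#' Full-precision CSV round-trip partner of [read_expression()]:
#' `read_expression(write_expression(df, path))` recovers `df` exactly.
#'
#' @param df expression tibble (genes + `label`, optional `.sample_id`).
#' @param path output path.
#' @param sep field separator, `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(df, path, sep = ",") {
  dec <- decompose_expression(df, "label", require_two_classes = FALSE)
  out <- as.data.frame(dec$X, optional = TRUE)
  out$label <- dec$labels_raw
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a two-class expression dataset
#'
#' Computes the counts and the two shape statistics standard in microarray
#' work: the sample-to-dimension ratio SDR = (n1 + n2) / n_genes (reported
#' as a percentage, rounded half away from zero) and the imbalance ratio
#' IR = majority count / minority count (>= 1, and 1 exactly when balanced).
#'
#' @param df expression tibble with a label column.
#' @param label_col label column name.
#' @param digits decimals for `sdr_percent` (shape tables in the field print
#'   1-2).
#' @return One-row tibble: `n_class1` (minority), `n_class2` (majority),
#'   `n_features`, `sdr` (fraction), `sdr_percent` (rounded), `ir` (exact).
#' @export
#' @examples
#' df <- simulate_expression(22, 40, 2000, seed = 1)$data
#' dataset_summary(df)   # SDR 3.1%, IR 1.82
dataset_summary <- function(df, label_col = "label", digits = 1) {
  dec <- decompose_expression(df, label_col)
  n1 <- sum(dec$y == -1)
  n2 <- sum(dec$y == 1)
  p <- ncol(dec$X)
  tibble::tibble(
    n_class1 = n1, n_class2 = n2, n_features = p,
    sdr = (n1 + n2) / p,
    sdr_percent = round_half_away(100 * (n1 + n2) / p, digits),
    ir = max(n1, n2) / min(n1, n2)
  )
}

#' Write a gene ranking to TSV
#'
#' @param ranking tibble with columns `gene_id`, `rank` (1 = most important;
#'   must be a permutation of `1:nrow`), and optionally
#'   `elimination_iteration`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(ranking, path) {
  stopifnot(is.data.frame(ranking),
            all(c("gene_id", "rank") %in% names(ranking)))
  if (nrow(ranking) > 0 && anyDuplicated(ranking$rank)) {
    abort("Duplicate ranks in selection output.")
  }
  if (nrow(ranking) > 0 && !setequal(ranking$rank, seq_len(nrow(ranking)))) {
    abort("`rank` must be a permutation of 1..n.")
  }
  if (!"elimination_iteration" %in% names(ranking)) {
    ranking$elimination_iteration <- NA_integer_
  }
  out <- ranking[order(ranking$rank),
                 c("gene_id", "rank", "elimination_iteration")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene ranking written by [write_selection()]
#' @param path TSV path.
#' @return tibble with `gene_id`, `rank`, `elimination_iteration`.
#' @export
read_selection <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  tibble::as_tibble(out)
}
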