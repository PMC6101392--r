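#' Run the full gene-selection workflow
#'
#' Chains the stages in the standard order — load (or simulate) the labeled
#' matrix, balance the classes with RVOS, standardize per gene on the
#' (balanced) data, optionally discretize, select genes by VSSRFE, and
#' evaluate the selected genes by stratified cross-validation — and writes
#' the artifact bundle: ranking TSV, selected-submatrix CSV, metrics JSON
#' and a run log with one line per elimination iteration.
#'
#' @param config named list (or path to a `key = value` text file parsed by
#'   [read_run_config()]) with entries:
#'   \describe{
#'     \item{input}{path to a CSV/TSV/ARFF dataset; omit to simulate.}
#'     \item{label_col}{label column name (default `"label"`).}
#'     \item{simulate_n_class1, simulate_n_class2, simulate_n_genes,
#'       simulate_n_informative, simulate_effect}{simulation shape used
#'       when `input` is absent (defaults 22/40/2000/10/2).}
#'     \item{seed}{integer; seeds balancing, selection and fold assignment
#'       (mandatory).}
#'     \item{balance}{apply RVOS balancing (default TRUE).}
#'     \item{standardize}{default TRUE; `ddof` 0 or 1 (default 0).}
#'     \item{discretize}{write a discretized copy as well (default FALSE).}
#'     \item{method}{`"vssrfe"` or `"rfe"` (default `"vssrfe"`).}
#'     \item{estimator}{`"llsvm"` (default) or `"svm"`.}
#'     \item{C}{LLSVM penalty (default 1).}
#'     \item{s_initial}{initial step size (default 100).}
#'     \item{n_selected}{genes to keep (default 10).}
#'     \item{classifier}{`"llsvm"` (default), `"svm"`, `"lr"`, `"knn"`,
#'       `"nb"`.}
#'     \item{folds}{CV fold count (default 5).}
#'     \item{out_dir}{output directory (created if needed).}
#'   }
#' @return Invisibly, a list with the trace, the cross-validation result,
#'   the dataset summaries, and the artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  cfg <- utils::modifyList(list(
    label_col = "label", simulate_n_class1 = 22, simulate_n_class2 = 40,
    simulate_n_genes = 2000, simulate_n_informative = 10,
    simulate_effect = 2, balance = TRUE, standardize = TRUE, ddof = 0,
    discretize = FALSE, method = "vssrfe", estimator = "llsvm", C = 1,
    s_initial = 100, n_selected = 10, classifier = "llsvm", folds = 5
  ), config)
  for (key in c("seed", "out_dir")) {
    if (is.null(cfg[[key]])) abort(sprintf("Config entry '%s' is required.", key))
  }
  if (!cfg$method %in% c("vssrfe", "rfe")) abort("method must be vssrfe or rfe.")
  if (!cfg$estimator %in% c("llsvm", "svm")) abort("estimator must be llsvm or svm.")
  if (!cfg$classifier %in% c("llsvm", "svm", "lr", "knn", "nb")) {
    abort("Unknown classifier.")
  }
  seed <- as.integer(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  cfg_hash <- sum(utf8ToInt(paste(names(cfg), sapply(cfg, paste,
                                                     collapse = ","),
                                  collapse = ";")))
  say("config_hash=%d seed=%d", cfg_hash, seed)

  df <- if (!is.null(cfg$input)) {
    say("stage=load input=%s", cfg$input)
    read_expression(cfg$input, label_col = cfg$label_col)
  } else {
    say("stage=simulate shape=%d/%d genes=%d", cfg$simulate_n_class1,
        cfg$simulate_n_class2, cfg$simulate_n_genes)
    simulate_expression(cfg$simulate_n_class1, cfg$simulate_n_class2,
                        cfg$simulate_n_genes,
                        n_informative = cfg$simulate_n_informative,
                        effect = cfg$simulate_effect, seed = seed)$data
  }
  summary_raw <- dataset_summary(df)
  say("stage=summary n1=%d n2=%d genes=%d ir=%.4f", summary_raw$n_class1,
      summary_raw$n_class2, summary_raw$n_features, summary_raw$ir)

  imbalance_warning <- FALSE
  if (isTRUE(cfg$balance)) {
    df <- rvos_balance(df, seed = seed)
    say("stage=balance ir=%.4f", dataset_summary(df)$ir)
  } else if (summary_raw$ir > 1) {
    imbalance_warning <- TRUE
    say("stage=balance skipped WARNING ir=%.4f > 1", summary_raw$ir)
  }

  if (isTRUE(cfg$standardize)) {
    std <- fit_standardizer(df, ddof = cfg$ddof)
    df <- apply_standardizer(df, std)
    say("stage=standardize ddof=%d", cfg$ddof)
    if (isTRUE(cfg$discretize)) {
      dsc <- discretize_expression(df)
      write_expression(dsc, file.path(cfg$out_dir, "discretized.csv"))
      say("stage=discretize written=discretized.csv")
    }
  }

  est <- if (cfg$estimator == "llsvm") llsvm_estimator(C = cfg$C) else {
    svm_estimator(cost = cfg$C)
  }
  s_init <- if (cfg$method == "rfe") 1L else as.integer(cfg$s_initial)
  trace <- vssrfe_select(df, n_selected = as.integer(cfg$n_selected),
                         s_initial = s_init, estimator = est, seed = seed)
  for (i in seq_len(nrow(trace$iterations))) {
    r <- trace$iterations[i, ]
    say("stage=select iteration=%d N=%d S=%d deleted=%d", r$iteration,
        r$n_remaining + r$n_deleted, r$step_size, r$n_deleted)
  }

  ranking_path <- file.path(cfg$out_dir, "ranking.tsv")
  write_selection(trace$ranking, ranking_path)
  sel_path <- file.path(cfg$out_dir, "selected.csv")
  sel_df <- df[c(trace$selected, "label")]
  write_expression(sel_df, sel_path)
  say("stage=artifacts ranking=%s selected=%s", basename(ranking_path),
      basename(sel_path))

  pipeline <- if (cfg$classifier == "llsvm") {
    llsvm_pipeline(C = cfg$C, standardize = FALSE)
  } else {
    classifier_pipeline(cfg$classifier, standardize = FALSE)
  }
  cv <- cross_validate(sel_df, pipeline, k = as.integer(cfg$folds),
                       seed = seed)
  say("stage=evaluate folds=%d acc=%.4f mcc=%.4f auc=%.4f", cv$k,
      cv$mean$acc, cv$mean$mcc, cv$mean$auc)

  metrics_path <- file.path(cfg$out_dir, "metrics.json")
  jsonlite::write_json(list(
    config_hash = cfg_hash, seed = seed,
    dataset = as.list(summary_raw),
    imbalance_warning = imbalance_warning,
    selected = trace$selected,
    mean = as.list(cv$mean),
    per_fold = cv$per_fold
  ), metrics_path, auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, log_path)

  invisible(list(trace = trace, cv = cv, summary = summary_raw,
                 imbalance_warning = imbalance_warning,
                 paths = c(ranking = ranking_path, selected = sel_path,
                           metrics = metrics_path, log = log_path)))
}

#' Read a flat `key = value` run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as logical/numeric where possible, otherwise kept as strings.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort(sprintf("Malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    out[[key]] <- if (toupper(val) %in% c("TRUE", "FALSE")) {
      as.logical(val)
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else {
      gsub('^"|"$', "", val)
    }
  }
  out
}
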