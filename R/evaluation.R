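#' Confusion counts for binary predictions
#'
#' @param truth,predicted equal-length vectors of binary class codes.
#' @param positive the class counted as positive (TP/FN side). For
#'   imbalanced expression data the minority class is the conventional
#'   choice.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  codes <- unique(truth)
  if (!as.character(positive) %in% codes) {
    abort("`positive` is not one of the observed classes.")
  }
  if (!all(predicted %in% codes)) {
    abort("`predicted` contains a label not present in `truth`.")
  }
  pos <- as.character(positive)
  tibble::tibble(
    tp = sum(truth == pos & predicted == pos),
    fp = sum(truth != pos & predicted == pos),
    tn = sum(truth != pos & predicted != pos),
    fn = sum(truth == pos & predicted != pos)
  )
}

#' Classification accuracy from confusion counts
#' @param counts one-row tibble/list with `tp`, `fp`, `tn`, `fn`.
#' @return (TP + TN) / (TP + FP + TN + FN).
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) abort("Empty confusion counts.")
  (counts$tp + counts$tn) / total
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), the
#' correlation between predicted and true binary labels: +1 for a perfect
#' prediction, 0 for a random one, -1 for a perfectly inverted one. When any
#' denominator factor is zero (all predictions or all truths one class) the
#' coefficient is undefined and 0 is returned.
#'
#' @inheritParams accuracy
#' @return MCC in [-1, 1].
#' @export
mcc <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fp + tn + fn == 0) abort("Empty confusion counts.")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' True and false positive rates
#' @inheritParams accuracy
#' @return One-row tibble with `tpr` = TP/(TP+FN) and `fpr` = FP/(FP+TN)
#'   (NaN when the corresponding class is absent).
#' @export
rates <- function(counts) {
  tibble::tibble(
    tpr = counts$tp / (counts$tp + counts$fn),
    fpr = counts$fp / (counts$fp + counts$tn)
  )
}

#' Rank-based AUC (Mann-Whitney)
#'
#' The probability that a randomly chosen positive sample scores higher
#' than a randomly chosen negative one, with tied pairs counted 1/2; this
#' equals the trapezoidal area under the ROC curve.
#'
#' @param scores numeric decision scores, larger = more positive.
#' @param truth class codes.
#' @param positive the positive class code.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, truth, positive) {
  if (length(scores) != length(truth)) {
    abort("`scores` and `truth` must have equal length.")
  }
  pos <- as.character(truth) == as.character(positive)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) abort("AUC needs both classes present.")
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metrics report
#'
#' @param truth,predicted class codes.
#' @param scores optional decision scores for AUC.
#' @param positive positive class code.
#' @return One-row tibble: `acc`, `mcc`, `auc` (NA without scores), `tpr`,
#'   `fpr`, and the confusion counts.
#' @export
metrics_report <- function(truth, predicted, scores = NULL, positive) {
  cc <- confusion_counts(truth, predicted, positive)
  r <- rates(cc)
  tibble::tibble(
    acc = accuracy(cc),
    mcc = mcc(cc),
    auc = if (is.null(scores)) NA_real_ else auc(scores, truth, positive),
    tpr = r$tpr,
    fpr = r$fpr,
    tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn
  )
}

#' Stratified k-fold assignment
#'
#' Shuffles the samples within each class (seeded) and deals them
#' round-robin over the folds, so per-fold class counts differ from exact
#' proportionality by at most one sample per class — the stratification
#' guarantee that keeps training and test class proportions equal.
#'
#' @param labels vector of class codes, one per sample.
#' @param k fold count (default 5, the domain's standard choice).
#' @param seed integer seed for the within-class shuffles.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k = 5, seed = NULL) {
  labels <- as.character(labels)
  k <- as.integer(k)
  if (k < 2) abort("`k` must be >= 2.")
  tab <- table(labels)
  if (any(tab < k)) {
    abort(sprintf("Class '%s' has fewer than k = %d samples.",
                  names(tab)[which.min(tab)], k))
  }
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Bundle a trainer and predictor into a cross-validation pipeline
#'
#' The pipeline contract: `fit(df)` receives the training rows only (label
#' column included) and returns any model object; `predict(model, df)`
#' receives the held-out rows and returns a list with `class` (codes) and
#' optionally `score` (numeric, for AUC). Preprocessing that must not leak
#' (standardization, balancing, selection) belongs inside `fit`.
#'
#' @param fit function(df) -> model.
#' @param predict function(model, df) -> list(class = ..., score = ...,
#'   score_class = ...); `score_class` names the class toward which larger
#'   scores point (absent means scores already point toward the evaluation's
#'   positive class). [cross_validate()] flips the sign when needed so AUC
#'   is always computed relative to the declared positive class.
#' @param label_col label column name.
#' @return A `cv_pipeline` object.
#' @export
new_pipeline <- function(fit, predict, label_col = "label") {
  structure(list(fit = fit, predict = predict, label_col = label_col),
            class = "cv_pipeline")
}

#' Standard LLSVM pipeline: standardize on train, fit, predict
#'
#' @param C penalty factor.
#' @param standardize standardize per gene using training-fold parameters.
#' @param balance apply [rvos_balance()] to the training fold first.
#' @param seed seed for the balancing draws.
#' @param ... further arguments to [llsvm()].
#' @return A `cv_pipeline`.
#' @export
llsvm_pipeline <- function(C = 1, standardize = TRUE, balance = FALSE,
                           seed = NULL, ...) {
  new_pipeline(
    fit = function(df) {
      if (balance) df <- rvos_balance(df, seed = seed)
      std <- if (standardize) fit_standardizer(df) else NULL
      if (!is.null(std)) df <- apply_standardizer(df, std)
      list(model = llsvm(df, C = C, ...), std = std)
    },
    predict = function(obj, df) {
      if (!is.null(obj$std)) df <- apply_standardizer(df, obj$std)
      list(class = predict(obj$model, df),
           score = decision_score(obj$model, df),
           score_class = unname(obj$model$label_map[["1"]]))
    }
  )
}

#' Off-the-shelf classifier pipelines behind the CV contract
#'
#' Adapters for the four standard baseline classifiers — linear SVM and
#' naive Bayes (e1071), k-nearest neighbours (class), and logistic
#' regression (stats::glm) — so they can be compared under the same
#' cross-validation harness. They are plumbing around established
#' implementations, not re-implementations.
#'
#' @param method one of `"svm"`, `"nb"`, `"knn"`, `"lr"`.
#' @param standardize standardize per gene on the training fold.
#' @param cost SVM cost (linear kernel).
#' @param k neighbours for kNN.
#' @return A `cv_pipeline`.
#' @export
classifier_pipeline <- function(method = c("svm", "nb", "knn", "lr"),
                                standardize = TRUE, cost = 1, k = 3) {
  method <- match.arg(method)
  if (method %in% c("svm", "nb") &&
      !requireNamespace("e1071", quietly = TRUE)) {
    abort("The e1071 package is required for this classifier.")
  }
  if (method == "knn" && !requireNamespace("class", quietly = TRUE)) {
    abort("The class package is required for kNN.")
  }
  split_xy <- function(df) {
    keep <- setdiff(names(df), c("label", ".sample_id"))
    list(X = as.matrix(df[keep]), y = factor(df$label))
  }
  new_pipeline(
    fit = function(df) {
      std <- if (standardize) fit_standardizer(df) else NULL
      if (!is.null(std)) df <- apply_standardizer(df, std)
      xy <- split_xy(df)
      model <- switch(method,
        svm = e1071::svm(xy$X, xy$y, kernel = "linear", cost = cost,
                         scale = FALSE, probability = FALSE),
        nb = e1071::naiveBayes(xy$X, xy$y),
        knn = xy,                        # kNN is lazy: keep the data
        lr = {
          dat <- data.frame(xy$X, check.names = FALSE)
          dat$.y <- as.integer(xy$y == levels(xy$y)[2])
          suppressWarnings(stats::glm(.y ~ ., data = dat,
                                      family = stats::binomial()))
        })
      list(model = model, std = std, levels = levels(xy$y))
    },
    predict = function(obj, df) {
      if (!is.null(obj$std)) df <- apply_standardizer(df, obj$std)
      xy <- split_xy(df)
      switch(method,
        svm = {
          dv <- attr(predict(obj$model, xy$X, decision.values = TRUE),
                     "decision.values")
          cls <- as.character(predict(obj$model, xy$X))
          # e1071 decision values are signed toward the class named first
          # in the "A/B" column label
          first <- strsplit(colnames(dv)[1], "/")[[1]][1]
          list(class = cls, score = drop(dv), score_class = first)
        },
        nb = {
          pr <- predict(obj$model, xy$X, type = "raw")
          list(class = colnames(pr)[max.col(pr)], score = pr[, 2],
               score_class = colnames(pr)[2])
        },
        knn = {
          pred <- class::knn(obj$model$X, xy$X, obj$model$y, k = k,
                             prob = TRUE)
          p_win <- attr(pred, "prob")
          score <- ifelse(pred == obj$levels[2], p_win, 1 - p_win)
          list(class = as.character(pred), score = score,
               score_class = obj$levels[2])
        },
        lr = {
          dat <- data.frame(xy$X, check.names = FALSE)
          # rank deficiency is the norm when genes outnumber samples
          p <- suppressWarnings(stats::predict(obj$model, newdata = dat,
                                               type = "response"))
          list(class = obj$levels[1 + (p >= 0.5)], score = unname(p),
               score_class = obj$levels[2])
        })
    }
  )
}

#' Stratified cross-validation of a pipeline
#'
#' For each fold, the pipeline's `fit` sees only the training rows (so any
#' preprocessing it performs is leakage-free by construction) and its
#' predictions on the held-out rows are scored. Metrics are reported per
#' fold and as their unweighted mean.
#'
#' @param df expression tibble with a two-class label column.
#' @param pipeline a `cv_pipeline` (e.g. [llsvm_pipeline()]).
#' @param k fold count.
#' @param seed seed for the fold assignment.
#' @param positive positive class; defaults to the minority class.
#' @param folds optional precomputed fold vector (overrides `k`/`seed`).
#' @return A `cv_result`: `tidy()` gives per-fold metrics, `glance()` the
#'   mean metrics across folds.
#' @export
cross_validate <- function(df, pipeline, k = 5, seed = NULL,
                           positive = NULL, folds = NULL) {
  stopifnot(inherits(pipeline, "cv_pipeline"))
  dec <- decompose_expression(df, pipeline$label_col)
  if (is.null(positive)) positive <- dec$minority
  if (is.null(folds)) {
    folds <- stratified_folds(dec$labels_raw, k = k, seed = seed)
  }
  stopifnot(length(folds) == nrow(df))
  per_fold <- purrr::map_dfr(sort(unique(folds)), function(f) {
    train <- df[folds != f, , drop = FALSE]
    test <- df[folds == f, , drop = FALSE]
    model <- tryCatch(pipeline$fit(train), error = function(e) {
      abort(sprintf("Pipeline fit failed on fold %d: %s", f,
                    conditionMessage(e)))
    })
    pred <- tryCatch(pipeline$predict(model, test), error = function(e) {
      abort(sprintf("Pipeline predict failed on fold %d: %s", f,
                    conditionMessage(e)))
    })
    truth <- as.character(test[[pipeline$label_col]])
    score <- pred$score
    if (!is.null(score) && !is.null(pred$score_class) &&
        as.character(pred$score_class) != as.character(positive)) {
      score <- -score
    }
    rep <- metrics_report(truth, pred$class, score, positive)
    dplyr::bind_cols(tibble::tibble(fold = f), rep)
  })
  mean_metrics <- dplyr::summarise(
    per_fold,
    dplyr::across(c("acc", "mcc", "auc", "tpr", "fpr"),
                  ~ mean(.x, na.rm = FALSE)))
  structure(
    list(per_fold = per_fold, mean = mean_metrics, k = length(unique(folds)),
         positive = positive),
    class = "cv_result"
  )
}

#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(k = x$k), x$mean)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold stratified CV (positive class '%s')\n",
              x$k, x$positive))
  cat(sprintf("  mean ACC %.4f | MCC %.4f | AUC %s\n", x$mean$acc,
              x$mean$mcc,
              if (is.na(x$mean$auc)) "NA" else sprintf("%.4f", x$mean$auc)))
  invisible(x)
}

#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold[c("fold", "acc", "mcc", "auc")],
                              -"fold", names_to = "metric",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold),
                                     y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "Fold", y = "Value",
                  title = "Per-fold cross-validation metrics") +
    ggplot2::theme_minimal()
}

#' Grid search over pipeline parameters by cross-validated accuracy
#'
#' Evaluates every combination of the supplied parameter values (in declared
#' order) with [cross_validate()] and selects the combination with the
#' highest mean accuracy; ties go to the earlier grid point, for
#' reproducibility. The same fold assignment is reused for every grid point.
#'
#' @param df expression tibble.
#' @param pipeline_factory function taking the grid parameters (by name)
#'   and returning a `cv_pipeline`.
#' @param grid named list of parameter value vectors.
#' @param k,seed,positive passed to [cross_validate()].
#' @return List with `best` (one-row tibble of the winning parameters and
#'   metrics) and `table` (one row per grid point, in evaluation order).
#' @export
grid_search <- function(df, pipeline_factory, grid, k = 5, seed = NULL,
                        positive = NULL) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    abort("`grid` must be a non-empty named list of value vectors.")
  }
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; declared order is preserved
  label_col <- "label"
  dec <- decompose_expression(df, label_col)
  folds <- stratified_folds(dec$labels_raw, k = k, seed = seed)
  rows <- purrr::map_dfr(seq_len(nrow(points)), function(i) {
    pars <- as.list(points[i, , drop = FALSE])
    cv <- cross_validate(df, do.call(pipeline_factory, pars),
                         positive = positive, folds = folds)
    dplyr::bind_cols(tibble::as_tibble(pars), cv$mean)
  })
  best_i <- which.max(rows$acc)          # which.max takes the first maximum
  list(best = rows[best_i, , drop = FALSE], table = rows)
}
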