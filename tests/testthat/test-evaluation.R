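test_that("confusion counts match a hand count and swap symmetry", {
  truth <- c("+", "+", "+", "+", "+", "-", "-", "-", "-", "-")
  pred <- c("+", "+", "+", "-", "-", "-", "-", "-", "-", "+")
  cc <- confusion_counts(truth, pred, positive = "+")
  expect_equal(as.list(cc), list(tp = 3L, fp = 1L, tn = 4L, fn = 2L))
  sw <- confusion_counts(truth, pred, positive = "-")
  expect_equal(as.list(sw), list(tp = 4L, fp = 2L, tn = 3L, fn = 1L))
  expect_equal(confusion_counts(truth, truth, "+")$fp, 0L)
  expect_equal(confusion_counts(truth, truth, "+")$fn, 0L)
  expect_error(confusion_counts(truth[1:3], pred, "+"), "length")
  expect_error(confusion_counts(truth, pred, "zzz"), "positive")
})

test_that("accuracy and MCC match the hand-worked example", {
  cc <- tibble::tibble(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(accuracy(cc), 0.7)
  expect_equal(mcc(cc), 10 / sqrt(600))
  r <- rates(cc)
  expect_equal(r$tpr, 3 / 5)
  expect_equal(r$fpr, 1 / 5)
  # perfect / inverted / degenerate
  expect_equal(mcc(tibble::tibble(tp = 5, fp = 0, tn = 5, fn = 0)), 1)
  expect_equal(mcc(tibble::tibble(tp = 0, fp = 5, tn = 0, fn = 5)), -1)
  expect_equal(mcc(tibble::tibble(tp = 5, fp = 5, tn = 0, fn = 0)), 0)
  expect_equal(accuracy(tibble::tibble(tp = 0, fp = 3, tn = 0, fn = 3)), 0)
})

test_that("MCC sign flips when predictions are inverted", {
  set.seed(77)
  truth <- sample(c("x", "y"), 30, replace = TRUE)
  pred <- sample(c("x", "y"), 30, replace = TRUE)
  inv <- ifelse(pred == "x", "y", "x")
  m1 <- mcc(confusion_counts(truth, pred, "x"))
  m2 <- mcc(confusion_counts(truth, inv, "x"))
  expect_equal(m1, -m2)
})

test_that("AUC equals brute-force pair counting", {
  expect_equal(auc(c(0.9, 0.8, 0.3), c("p", "p", "n"), "p"), 1)
  expect_equal(auc(rep(0.5, 6), rep(c("p", "n"), 3), "p"), 0.5)
  expect_equal(auc(c(0.8, 0.4, 0.6, 0.2), c("p", "p", "n", "n"), "p"), 0.75)
  set.seed(81)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    truth <- c("p", "n", sample(c("p", "n"), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)   # coarse scores force some ties
    expect_equal(auc(scores, truth, "p"), oracle_auc(scores, truth, "p"))
    # complement identity (holds with midrank tie handling too)
    expect_equal(auc(scores, truth, "p") + auc(-scores, truth, "p"), 1)
  }
  expect_error(auc(1:3, rep("p", 3), "p"), "both classes")
})

test_that("metrics are invariant to sample permutation", {
  set.seed(83)
  truth <- sample(c("a", "b"), 40, replace = TRUE)
  pred <- sample(c("a", "b"), 40, replace = TRUE)
  scores <- rnorm(40)
  perm <- sample(40)
  r1 <- metrics_report(truth, pred, scores, "a")
  r2 <- metrics_report(truth[perm], pred[perm], scores[perm], "a")
  expect_equal(r1, r2)
})

test_that("stratified folds keep class proportions within one sample", {
  # divisible case: 40/40 into 5 folds -> exactly 8 + 8 per fold
  labs <- rep(c("a", "b"), each = 40)
  f <- stratified_folds(labs, k = 5, seed = 1)
  tab <- table(f, labs)
  expect_true(all(tab == 8))
  # 21/39 split
  labs2 <- rep(c("a", "b"), c(21, 39))
  f2 <- stratified_folds(labs2, k = 5, seed = 2)
  tab2 <- table(f2, labs2)
  expect_true(all(tab2[, "a"] %in% c(4, 5)))   # 21/5 = 4.2
  expect_true(all(tab2[, "b"] %in% c(7, 8)))   # 39/5 = 7.8
  expect_equal(sum(tab2), 60)
  # determinism
  expect_identical(f2, stratified_folds(labs2, k = 5, seed = 2))
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 30)), k = 5), "fewer")
})

test_that("cross-validation scores a separable pipeline perfectly", {
  sim <- simulate_expression(15, 15, 60, n_informative = 8, effect = 3,
                             seed = 19)
  cv <- cross_validate(sim$data, llsvm_pipeline(C = 1), k = 5, seed = 3)
  g <- glance(cv)
  expect_equal(g$acc, 1)
  expect_equal(g$mcc, 1)
  expect_equal(g$auc, 1)
  expect_equal(nrow(tidy(cv)), 5)
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("constant and memorizing pipelines bound the harness", {
  df <- simulate_expression(10, 10, 5, n_informative = 0, effect = 0,
                            seed = 23)$data
  const <- new_pipeline(
    fit = function(train) unique(train$label)[1],
    predict = function(m, test) list(class = rep(m, nrow(test))))
  cv <- cross_validate(df, const, k = 5, seed = 1)
  expect_equal(glance(cv)$acc, 0.5)
  # memorizer evaluated on its own training rows -> perfect (leakage probe)
  mem <- new_pipeline(
    fit = function(train) train,
    predict = function(m, test) {
      key <- apply(test[paste0("g", 1:5)], 1, paste, collapse = ",")
      mkey <- apply(m[paste0("g", 1:5)], 1, paste, collapse = ",")
      list(class = ifelse(key %in% mkey, m$label[match(key, mkey)],
                          "class1"))
    })
  folds <- stratified_folds(df$label, 5, seed = 2)
  mem_fit <- mem$fit(df)
  self <- mem$predict(mem_fit, df)
  expect_equal(mean(self$class == df$label), 1)
})

test_that("held-out rows never reach the pipeline fit", {
  df <- simulate_expression(10, 10, 4, n_informative = 2, seed = 29)$data
  seen <- list()
  probe <- new_pipeline(
    fit = function(train) {
      seen[[length(seen) + 1]] <<- sort(train$.sample_id)
      llsvm(train, C = 1)
    },
    predict = function(m, test) list(class = predict(m, test)))
  folds <- stratified_folds(df$label, k = 5, seed = 4)
  cross_validate(df, probe, folds = folds)
  for (f in 1:5) {
    held_out <- df$.sample_id[folds == f]
    expect_length(intersect(seen[[f]], held_out), 0)
  }
})

test_that("grid search picks the working penalty and keeps the table", {
  sim <- simulate_expression(10, 10, 30, n_informative = 6, effect = 3,
                             seed = 37)
  gs <- grid_search(sim$data, function(C) llsvm_pipeline(C = C),
                    grid = list(C = c(1e-9, 1)), k = 5, seed = 5)
  expect_equal(nrow(gs$table), 2)
  expect_equal(gs$best$C, 1)      # C = 1e-9 forces w = 0, ACC 0.5
  expect_lt(gs$table$acc[gs$table$C == 1e-9], gs$best$acc)
  # single-point grid returns that point
  gs1 <- grid_search(sim$data, function(C) llsvm_pipeline(C = C),
                     grid = list(C = 0.5), k = 5, seed = 5)
  expect_equal(gs1$best$C, 0.5)
  expect_error(grid_search(sim$data, function(C) llsvm_pipeline(C = C),
                           grid = list()), "non-empty")
})

test_that("external classifier adapters run under the same harness", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("class")
  sim <- simulate_expression(12, 12, 20, n_informative = 6, effect = 3,
                             seed = 43)
  for (m in c("svm", "nb", "knn", "lr")) {
    cv <- cross_validate(sim$data, classifier_pipeline(m), k = 4, seed = 6)
    expect_gte(glance(cv)$acc, 0.75)
    expect_gte(glance(cv)$auc, 0.75)
  }
})
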