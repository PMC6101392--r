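two_point <- function() list(X = matrix(c(1, -1), 2, 1), y = c(1, -1))

test_that("objective matches the definition on hand-worked cases", {
  tp <- two_point()
  # w = 0: every margin is 1, objective C * n
  expect_equal(llsvm_objective(0, tp$X, tp$y, C = 3), 6)
  # w = 0.75: 0.75 + 2 * 0.25^2
  expect_equal(llsvm_objective(0.75, tp$X, tp$y, C = 1), 0.875)
  # all margins >= 1 -> pure L1 term
  expect_equal(llsvm_objective(2, tp$X, tp$y, C = 10), 2)
  # random cases against the independent loop oracle
  set.seed(13)
  for (i in 1:20) {
    X <- matrix(rnorm(15), 5, 3)
    y <- sample(c(-1, 1), 5, replace = TRUE)
    w <- rnorm(3)
    expect_equal(llsvm_objective(w, X, y, 0.7),
                 oracle_objective(w, X, y, 0.7), tolerance = 1e-12)
  }
})

test_that("subproblem derivatives follow the active-set formulas", {
  tp <- two_point()
  d <- llsvm_derivatives(1, 0, tp$X, tp$y, C = 1)
  expect_equal(unname(d), c(-4, 4))
  # empty active set -> d1 = 0, floor engages
  d0 <- llsvm_derivatives(1, 5, tp$X, tp$y, C = 1)
  expect_equal(unname(d0), c(0, 1e-12))
  # linear in C while the floor is inactive
  d2 <- llsvm_derivatives(1, 0, tp$X, tp$y, C = 2)
  expect_equal(unname(d2), 2 * unname(d))
})

test_that("closed-form subproblem matches the 1-D grid oracle", {
  expect_equal(solve_subproblem(0, 0, 1), 0)
  expect_equal(solve_subproblem(0, -3, 2), 1)
  expect_equal(solve_subproblem(0.5, 0.2, 1), -0.5)
  set.seed(21)
  for (i in 1:200) {
    # ranges keep the true minimizer inside the oracle's [-10, 10] grid
    w_j <- runif(1, -2, 2)
    d1 <- runif(1, -5, 5)
    d2 <- runif(1, 0.7, 5)
    expect_lt(abs(solve_subproblem(w_j, d1, d2) -
                    oracle_subproblem_min(w_j, d1, d2)), 1e-4)
  }
  expect_error(solve_subproblem(0, 1, 0), "positive")
})

test_that("fit solves the two-point problem and the sparsity limit", {
  tp <- two_point()
  fit <- llsvm_fit_matrix(tp$X, tp$y, C = 1, tol = 1e-8)
  expect_equal(unname(fit$weights), 0.75, tolerance = 1e-6)
  expect_equal(fit$objective_trace[length(fit$objective_trace)], 0.875,
               tolerance = 1e-8)
  expect_true(fit$converged)
  # C -> 0 collapses every weight to exactly zero
  fit0 <- llsvm_fit_matrix(tp$X, tp$y, C = 1e-9)
  expect_identical(unname(fit0$weights), 0)
  set.seed(2)
  X <- matrix(rnorm(40), 8, 5)
  y <- rep(c(-1, 1), 4)
  expect_identical(unname(llsvm_fit_matrix(X, y, C = 1e-9)$weights),
                   rep(0, 5))
})

test_that("objective trace is non-increasing and below the start", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    fit <- llsvm_fit_matrix(X, y, C = sample(c(0.1, 1, 10), 1))
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
    expect_lte(fit$objective_trace[length(fit$objective_trace)],
               fit$objective_trace[1])
  }
})

test_that("fitted objective matches the convex grid oracle on tiny cases", {
  set.seed(41)
  for (i in 1:6) {
    n <- sample(3:5, 1)
    p <- sample(2:3, 1)
    # sd 2 keeps the optimal weights well inside the oracle's cube
    X <- matrix(rnorm(n * p, sd = 2), n, p)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.1, 1, 10), 1)
    fit <- llsvm_fit_matrix(X, y, C = C, tol = 1e-9, max_sweeps = 5000)
    oracle <- oracle_grid_min(X, y, C)
    obj <- fit$objective_trace[length(fit$objective_trace)]
    # the fit can never beat the true minimum, so this bound alone proves
    # optimality; the two-sided check needs the oracle argmin interior
    expect_lte(obj, oracle$obj + 1e-4)
    if (oracle$interior) {
      expect_equal(obj, oracle$obj, tolerance = 1e-4)
    }
  }
})

test_that("subdifferential optimality certificate holds at convergence", {
  set.seed(51)
  tol <- 1e-8
  for (i in 1:10) {
    n <- sample(4:10, 1)
    p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.1, 1, 5), 1)
    fit <- llsvm_fit_matrix(X, y, C = C, tol = tol, max_sweeps = 20000)
    w <- unname(fit$weights)
    cert_tol <- 1e-4
    for (j in seq_len(p)) {
      d <- llsvm_derivatives(j, w, X, y, C)
      if (w[j] == 0) {
        expect_lte(abs(d[["d1"]]), 1 + cert_tol)
      } else {
        expect_lte(abs(d[["d1"]] + sign(w[j])), cert_tol)
      }
    }
  }
})

test_that("separable shifted-Gaussian data is fit to training accuracy 1", {
  sim <- simulate_expression(20, 20, 50, n_informative = 5, effect = 3,
                             noise_sd = 1, seed = 8)
  fit <- llsvm(sim$data, C = 1)
  pred <- predict(fit, sim$data)
  expect_equal(mean(pred == sim$data$label), 1)
})

test_that("prediction is a sign rule with +1 ties, scale-invariant", {
  fit <- structure(list(weights = c(g1 = 1, g2 = -1), penalty = 1,
                        objective_trace = 1, n_sweeps_run = 1,
                        converged = TRUE, gene_ids = c("g1", "g2")),
                   class = "llsvm")
  X <- rbind(c(2, 0.5), c(0, 0), c(-1, 3))
  colnames(X) <- c("g1", "g2")
  expect_equal(predict(fit, X), c(1, 1, -1))   # zero score -> +1 side
  expect_equal(decision_score(fit, X), c(1.5, 0, -4))
  fit2 <- fit
  fit2$weights <- fit$weights * 17
  expect_equal(predict(fit2, X), predict(fit, X))
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- simulate_expression(8, 8, 12, n_informative = 3, effect = 3,
                             seed = 14)
  fit <- llsvm(sim$data, C = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 12)
  expect_named(td, c("gene_id", "weight", "abs_weight"))
  gl <- glance(fit)
  expect_equal(gl$n_nonzero, sum(td$weight != 0))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_error(llsvm_fit_matrix(matrix(1, 2, 1), c(1, 1), C = 1), "class")
})
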