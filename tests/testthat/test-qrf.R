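test_that("a single one-leaf tree reproduces inf-type empirical quantiles exactly", {
  set.seed(91)
  n <- 50
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n)
  expect_warning(
    fit <- qrf(cbind(rep(1, n), rep(2, n)), rep(3, n), n_trees = 2,
               seed = 1),
    "constant response")
  fit <- qrf(X, y, n_trees = 1, min_node_size = n, bootstrap = FALSE,
             seed = 1)
  expect_equal(length(fit$trees[[1]]$split_var), 1L)  # degenerate tree
  taus <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  got <- predict(fit, X[1:3, ], tau = taus)
  ys <- sort(y)
  emp <- sapply(taus, function(tau) ys[ceiling(tau * n)])
  for (i in 1:3) expect_equal(unname(got[i, ]), emp)
})

test_that("the strongest feature is found by the split search and dominates importance", {
  set.seed(92)
  n <- 200
  X <- cbind(step = rbinom(n, 1, 0.5), noise1 = rnorm(n),
             noise2 = rnorm(n))
  y <- 5 * X[, "step"] + rnorm(n, sd = 0.1)   # near-deterministic step
  fit <- qrf(X, y, n_trees = 100, mtry = 3, seed = 2)
  roots <- vapply(fit$trees, function(tr) tr$split_var[1], integer(1))
  expect_gte(mean(roots == 0L), 0.95)   # 0-based index of "step"
  imp <- variable_importance(fit, seed = 3)
  expect_equal(imp$feature[1], "step")
  expect_equal(imp$feature[which.max(imp$inc_node_purity)], "step")
  expect_true(all(imp$inc_node_purity >= 0))
})

test_that("forests are identical under the same seed", {
  set.seed(93)
  X <- matrix(rnorm(100 * 3), 100, 3)
  y <- X[, 1] + rnorm(100)
  f1 <- qrf(X, y, n_trees = 20, seed = 7)
  f2 <- qrf(X, y, n_trees = 20, seed = 7)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$inbag, f2$inbag)
})

test_that("leaf weights are a proper distribution and quantiles are monotone training values", {
  set.seed(94)
  X <- matrix(rnorm(150 * 3), 150, 3)
  y <- X[, 1] + rnorm(150)
  fit <- qrf(X, y, n_trees = 50, seed = 8)
  Xt <- matrix(rnorm(20 * 3), 20, 3)
  w <- qrf_weights(fit, Xt)
  expect_equal(rowSums(w), rep(1, 20), tolerance = 1e-10)
  expect_true(all(w >= 0))
  q <- predict(fit, Xt, tau = c(0.05, 0.5, 0.95))
  expect_true(all(q[, 1] <= q[, 2] & q[, 2] <= q[, 3]))
  expect_true(all(q %in% y))   # quantiles are training responses
  expect_error(predict(fit, Xt, tau = 1.2), "strictly in")
})

test_that("the conditional median tracks the true regression function", {
  # univariate median curve: large leaves smooth the per-point noise of
  # the weighted empirical CDF; the closed-form conditional median is x
  set.seed(95)
  n <- 5000
  X <- matrix(runif(n, -2, 2), n, 1)
  y <- X[, 1] + rnorm(n)
  fit <- qrf(X, y, n_trees = 300, mtry = 1, min_node_size = 60, seed = 9)
  grid <- matrix(seq(-1, 1, by = 0.05), ncol = 1)
  med <- predict(fit, grid, tau = 0.5)
  expect_lt(mean(abs(med - grid[, 1])), 0.15)
})

test_that("interval width follows heteroscedastic noise", {
  set.seed(96)
  n <- 3000
  X <- matrix(runif(n, 0, 1), n, 1)
  y <- rnorm(n, sd = 0.2 + X[, 1])
  fit <- qrf(X, y, n_trees = 100, mtry = 1, seed = 10)
  Xt <- matrix(runif(500, 0, 1), ncol = 1)
  pi <- prediction_interval(fit, Xt)
  width <- pi$upper - pi$lower
  expect_gt(cor(width, Xt[, 1], method = "spearman"), 0.5)
})

test_that("90% intervals are calibrated on held-out homoscedastic data across seeds", {
  cov_seed <- function(s) {
    set.seed(s)
    n <- 2000
    p <- 5
    X <- matrix(rnorm((n + 5000) * p), n + 5000, p)
    y <- X %*% rep(0.4, p) + rnorm(n + 5000)
    fit <- qrf(X[1:n, ], y[1:n], n_trees = 150, seed = s)
    pi <- prediction_interval(fit, X[-(1:n), ])
    yt <- y[-(1:n)]
    100 * mean(yt >= pi$lower & yt <= pi$upper)
  }
  covs <- vapply(101:105, cov_seed, numeric(1))
  expect_true(all(covs >= 87 & covs <= 93))
})

test_that("permutation importance vanishes for noise features and under a permuted response", {
  # %IncMSE of a pure-noise feature stays near zero across seeds
  incs <- vapply(1:20, function(s) {
    set.seed(s)
    X <- cbind(signal = rnorm(300), noise = rnorm(300))
    y <- X[, "signal"] + rnorm(300, sd = 0.5)
    fit <- qrf(X, y, n_trees = 60, mtry = 2, seed = s)
    imp <- variable_importance(fit, seed = s)
    imp$inc_mse_pct[imp$feature == "noise"]
  }, numeric(1))
  expect_lt(abs(mean(incs)), 2)
  # permuting y before fitting kills all importances
  set.seed(97)
  X <- matrix(rnorm(300 * 3), 300, 3)
  y <- sample(X[, 1] + rnorm(300))
  fit <- qrf(X, y, n_trees = 200, seed = 11)
  imp <- variable_importance(fit, seed = 12)
  expect_lt(max(abs(imp$inc_mse_pct)), 6)
})

test_that("models survive a JSON round trip with identical quantile predictions", {
  set.seed(98)
  X <- matrix(rnorm(80 * 3), 80, 3)
  y <- X[, 1] + rnorm(80)
  fit <- qrf(X, y, n_trees = 15, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  qrf_to_json(fit, path)
  back <- qrf_from_json(path)
  Xt <- matrix(rnorm(10 * 3), 10, 3)
  expect_equal(predict(back, Xt, tau = c(0.1, 0.5, 0.9)),
               predict(fit, Xt, tau = c(0.1, 0.5, 0.9)))
})
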