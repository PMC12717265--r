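test_that("regression trees handle degenerate and step-function data", {
  # constant response: a single leaf
  X <- matrix(1:8, 8, 1)
  tr <- fit_tree(X, rep(0.4, 8))
  expect_true(tr$root$leaf)
  expect_equal(predict(tr, X), rep(0.4, 8))
  # a clean step in one feature is found exactly at depth 1
  X2 <- cbind(c(1, 2, 3, 10, 11, 12))
  y2 <- c(0, 0, 0, 1, 1, 1)
  tr2 <- fit_tree(X2, y2, max_depth = 1, min_leaf = 1)
  expect_false(tr2$root$leaf)
  expect_equal(tr2$root$threshold, 6.5)
  expect_equal(tr2$root$left$value, 0)
  expect_equal(tr2$root$right$value, 1)
  expect_equal(predict(tr2, cbind(c(2, 11))), c(0, 1))
  # min_leaf is respected
  tr3 <- fit_tree(cbind(1:6), c(0, 0, 0, 1, 1, 1), max_depth = 3, min_leaf = 3)
  expect_true(tr3$root$left$leaf && tr3$root$right$leaf)
})

test_that("greedy splitting equals the exhaustive-search oracle", {
  set.seed(3)
  for (i in 1:60) {
    n <- sample(4:12, 1); p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    md <- sample(1:3, 1); ml <- sample(1:2, 1)
    tr <- fit_tree(X, y, max_depth = md, min_leaf = ml)
    expect_equal(sum((y - predict(tr, X))^2),
                 greedy_oracle_sse(X, y, md, ml), tolerance = 1e-9)
  }
})

test_that("LSBoost interpolates, degenerates and descends as expected", {
  set.seed(9)
  X <- matrix(rnorm(40), 20, 2)
  y <- X[, 1] + 0.3 * X[, 2]^2 + rnorm(20, 0, 0.05)
  # one full-strength deep stage memorizes the data
  m1 <- fit_lsboost(X, y, n_stages = 1, nu = 1, max_depth = 30, min_leaf = 1)
  expect_equal(predict(m1, X), y, tolerance = 1e-9)
  # an empty ensemble predicts the mean
  m0 <- fit_lsboost(X, y, n_stages = 0)
  expect_equal(predict(m0, X), rep(mean(y), 20))
  # training MSE is monotone non-increasing over 50 stages
  m <- fit_lsboost(X, y, n_stages = 50, nu = 0.1, max_depth = 2, min_leaf = 2)
  expect_true(all(diff(m$train_mse) <= 1e-12))
})

test_that("ensemble predictions are the shrunken sum over stages", {
  set.seed(10)
  X <- matrix(rnorm(60), 30, 2)
  y <- rnorm(30)
  m <- fit_lsboost(X, y, n_stages = 7, nu = 0.25, max_depth = 2, min_leaf = 3)
  Xnew <- matrix(rnorm(10), 5, 2)
  manual <- rep(m$f0, 5)
  for (tr in m$trees) manual <- manual + m$nu * predict(tr, Xnew)
  expect_equal(predict(m, Xnew), manual, tolerance = 1e-12)
  expect_error(predict(m, matrix(0, 2, 3)), "feature count")
})

test_that("split-gain importance finds planted signals and normalizes", {
  set.seed(11)
  X <- matrix(rnorm(500), 100, 5)
  y <- 2 * X[, 2] + rnorm(100, 0, 0.1)
  m <- fit_lsboost(X, y, n_stages = 30, nu = 0.2, max_depth = 2, min_leaf = 5)
  imp <- feature_importance(m)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_gt(imp[2], 0.9)
  # single-feature data: importance 1 on that feature
  m1 <- fit_lsboost(cbind(rnorm(50)), rnorm(50), n_stages = 5, max_depth = 2,
                    min_leaf = 5)
  expect_equal(unname(feature_importance(m1)[1]), 1, tolerance = 1e-9)
})

test_that("the external booster adapter honours the shared contract", {
  skip_if_not_installed("xgboost")
  set.seed(12)
  X <- matrix(rnorm(300), 100, 3)
  colnames(X) <- c("a", "b", "c")
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(100, 0, 0.05)
  m <- fit_xgboost(X, y, nrounds = 50, seed = 4)
  # determinism
  m2 <- fit_xgboost(X, y, nrounds = 50, seed = 4)
  expect_identical(predict(m, X), predict(m2, X))
  # constant response is fitted to numerical tolerance
  mc <- fit_xgboost(X, rep(0.25, 100), nrounds = 20)
  expect_equal(predict(mc, X), rep(0.25, 100), tolerance = 1e-6)
  # importance normalizes over named features
  imp <- feature_importance(m)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_named(imp, c("a", "b", "c"))
  expect_gt(imp["a"], imp["b"])
})

test_that("boosting routes agree on the synthetic cohort", {
  skip_if_not_installed("xgboost")
  co <- generate_cohort(60, seed = 5, missing_va = 0)
  tab <- build_observation_table(co)
  sp <- split_train_test(tab, 0.8, seed = 2)
  Xtr <- observation_features(sp$train, 9, use_aa = TRUE)
  Xte <- observation_features(sp$test, 9, use_aa = TRUE)
  ls <- fit_lsboost(Xtr, sp$train$va)
  xg <- fit_xgboost(Xtr, sp$train$va, seed = 1)
  r_ls <- evaluate(sp$test$va, predict(ls, Xte))$rmse
  r_xg <- evaluate(sp$test$va, predict(xg, Xte))$rmse
  expect_lt(abs(r_xg - r_ls) / r_ls, 0.25)
})
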