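test_that("a constant response yields a single-leaf tree", {
  X <- matrix(runif(20), 10, 2)
  tree <- build_tree(X, rep(3.5, 10))
  expect_equal(nrow(tree), 1)
  expect_equal(tree[1, "var"], c(var = 0))
  expect_equal(tree[1, "value"], c(value = 3.5))
  expect_equal(predict(tree, X), rep(3.5, 10))
})

test_that("a perfectly separating binary covariate is split at the root", {
  X <- data.frame(a = c(0, 0, 1, 1), b = c(0.1, 0.9, 0.4, 0.6))
  y <- c(0, 0, 1, 1)
  tree <- build_tree(X, y, mtry = 2, min_node_size = 1)
  expect_equal(unname(tree[1, "var"]), 1)
  expect_equal(unname(tree[1, "split"]), 0.5)
  expect_equal(sort(unique(predict(tree, X))), c(0, 1))
})

test_that("the engine's root split equals the exhaustive brute-force split", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    p <- sample(2:4, 1)
    X <- matrix(runif(n * p), n, p)
    y <- runif(n)
    tree <- build_tree(X, y, mtry = p, min_node_size = 2)
    oracle <- brute_force_split(X, y)
    expect_equal(unname(tree[1, "var"]), oracle$var)
    expect_equal(unname(tree[1, "split"]), oracle$split, tolerance = 1e-12)
  }
})

test_that("a full tree with mtry = p reproduces exhaustive CART predictions", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    p <- sample(2:4, 1)
    X <- matrix(runif(n * p), n, p)
    y <- runif(n)
    tree <- build_tree(X, y, mtry = p, min_node_size = 5)
    expect_equal(predict(tree, X), brute_force_cart_predict(X, y, 5L))
  }
})

test_that("forest predictions, OOB error and reruns are deterministic", {
  set.seed(30)
  X <- data.frame(x1 = runif(60), x2 = runif(60))
  y <- X$x1 + rnorm(60, 0, 0.2)
  f1 <- fit_forest(X, y, n_trees = 100, mtry = 1, seed = 5)
  f2 <- fit_forest(X, y, n_trees = 100, mtry = 1, seed = 5)
  expect_identical(f1$oob_mse, f2$oob_mse)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_lt(f1$oob_mse, var(y))  # the forest explains signal
})

test_that("a constant-response forest predicts the constant exactly", {
  X <- data.frame(x1 = runif(30), x2 = runif(30))
  f <- fit_forest(X, rep(2.25, 30), n_trees = 50, mtry = 1, seed = 1)
  expect_equal(predict(f, X), rep(2.25, 30))
  expect_equal(f$oob_mse, 0)
})

test_that("mtry larger than p is rejected", {
  X <- data.frame(x1 = runif(20), x2 = runif(20))
  expect_error(fit_forest(X, runif(20), n_trees = 10, mtry = 3), "mtry")
})

test_that("single-tree OOB error is computed over that tree's OOB rows", {
  set.seed(31)
  X <- data.frame(x1 = runif(40))
  y <- runif(40)
  f <- suppressWarnings(fit_forest(X, y, n_trees = 1, mtry = 1, seed = 2))
  oob_rows <- which(f$inbag[, 1] == 0)
  manual <- mean((y[oob_rows] -
                    predict(f, X[oob_rows, , drop = FALSE]))^2)
  expect_equal(oob_mse(f), manual)
})

test_that("a covariate absent from every tree has zero importance", {
  set.seed(32)
  X <- data.frame(x1 = runif(50), dead = rep(1, 50))  # constant, never split
  y <- X$x1
  f <- fit_forest(X, y, n_trees = 50, mtry = 2, seed = 3)
  imp <- permutation_importance(f, seed = 4)
  expect_equal(imp$importance[imp$predictor == "dead"], 0)
})

test_that("duplicated signal covariates outrank null covariates", {
  set.seed(33)
  n <- 150
  x <- runif(n)
  X <- data.frame(s1 = x, s2 = x + rnorm(n, 0, 0.01),
                  n1 = runif(n), n2 = runif(n), n3 = runif(n))
  y <- 2 * x + rnorm(n, 0, 0.1)
  f <- fit_forest(X, y, n_trees = 200, mtry = 2, seed = 6)
  imp <- permutation_importance(f, seed = 7)
  ranks <- setNames(rank(-imp$importance), imp$predictor)[names(X)]
  expect_lt(max(ranks[c("s1", "s2")]), min(ranks[c("n1", "n2", "n3")]))
})

test_that("partial dependence equals the brute-force force-and-average oracle", {
  set.seed(34)
  X <- data.frame(x1 = runif(80), x2 = runif(80), x3 = runif(80))
  y <- sin(2 * pi * X$x1) + X$x2 + rnorm(80, 0, 0.1)
  f <- fit_forest(X, y, n_trees = 100, mtry = 2, seed = 8)
  grid <- c(0.25, 0.5, 0.75)
  pd <- partial_dependence(f, "x1", grid = grid)
  manual <- vapply(grid, function(g) {
    Xg <- X
    Xg$x1 <- g
    mean(predict(f, Xg))
  }, numeric(1))
  expect_identical(pd$yhat, manual)
})

test_that("partial dependence of a constant model is flat", {
  X <- data.frame(x1 = runif(40), x2 = runif(40))
  f <- fit_forest(X, rep(1.5, 40), n_trees = 30, mtry = 1, seed = 9)
  pd <- partial_dependence(f, "x1")
  expect_equal(pd$yhat, rep(1.5, nrow(pd)))
})

test_that("partial dependence is monotone where the additive signal is", {
  set.seed(35)
  n <- 300
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 3 * X$x1 + sin(2 * pi * X$x2) + rnorm(n, 0, 0.1)
  f <- fit_forest(X, y, n_trees = 300, mtry = 2, seed = 10)
  pd <- partial_dependence(f, "x1", grid = seq(0.1, 0.9, length.out = 9))
  expect_true(all(diff(pd$yhat) > 0))
})

test_that("PD averaged over the covariate's empirical values tracks the mean prediction", {
  # not an exact identity (it is a double average), but for a near-additive
  # fit the two agree closely
  set.seed(40)
  n <- 200
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 2 * X$x1 + X$x2 + rnorm(n, 0, 0.1)
  f <- fit_forest(X, y, n_trees = 200, mtry = 2, seed = 17)
  pd <- partial_dependence(f, "x1", grid = sort(X$x1))
  avg_pd <- mean(pd$yhat[match(X$x1, pd$grid)])
  expect_equal(avg_pd, mean(predict(f, X)), tolerance = 0.02)
})

test_that("grid values outside the observed range are truncated with a warning", {
  X <- data.frame(x1 = runif(30), x2 = runif(30))
  f <- fit_forest(X, X$x1, n_trees = 20, mtry = 1, seed = 11)
  expect_warning(pd <- partial_dependence(f, "x1", grid = c(-5, 0.5, 5)),
                 "truncated")
  expect_true(all(pd$grid >= min(X$x1) & pd$grid <= max(X$x1)))
})

test_that("per-group partial dependence averages over subgroup rows only", {
  set.seed(36)
  X <- data.frame(x1 = runif(60), x2 = runif(60))
  g <- factor(rep(c("A", "B"), each = 30))
  y <- X$x1 + ifelse(g == "A", 0, 1)
  f <- fit_forest(X, y, n_trees = 50, mtry = 1, seed = 12)
  pd <- partial_dependence(f, "x1", grid = 0.5, groups = g)
  Xg <- X
  Xg$x1 <- 0.5
  pr <- predict(f, Xg)
  expect_equal(pd$yhat_A, mean(pr[g == "A"]))
  expect_equal(pd$yhat_B, mean(pr[g == "B"]))
})

test_that("marginal means report the level difference against the 95% span", {
  set.seed(37)
  n <- 200
  X <- data.frame(flag = rep(c(FALSE, TRUE), n / 2), x = runif(n))
  y <- as.numeric(X$flag)  # pure step: responses are exactly 0 or 1
  f <- fit_forest(X, y, n_trees = 200, mtry = 2, seed = 13)
  mm <- marginal_means(f, "flag")
  expect_equal(mm$span95, 1)  # central 95% interval of {0,1} responses
  expect_equal(mm$mean_level1 - mm$mean_level0, 1, tolerance = 0.05)
  expect_equal(mm$pct_diff, 100, tolerance = 5)
  # identical level means give zero difference
  f0 <- fit_forest(X, rep(1, n), n_trees = 20, mtry = 2, seed = 14)
  mm0 <- marginal_means(f0, "flag")
  expect_equal(mm0$pct_diff, 0)
  expect_error(marginal_means(f, "x"), "two-level")
})

test_that("mtry diagnostic reports the rule-of-thumb anchors for p = 11", {
  set.seed(38)
  n <- 40
  X <- as.data.frame(matrix(runif(n * 11), n, 11))
  y <- 2 * X$V1 + rnorm(n, 0, 0.1)
  diag <- mtry_diagnostic(X, y, mtry_values = c(1, 11), n_trees = 150, seed = 15)
  expect_equal(unname(diag$anchors["p_over_3"]), 3.67)
  expect_equal(unname(diag$anchors["sqrt_p"]), 3.32)
  # greedy search finds the single strong signal at large mtry
  mse <- setNames(diag$table$oob_mse, diag$table$mtry)
  expect_lte(mse[["11"]], mse[["1"]])
})

test_that("rough imputation fills medians and modes and keeps the mask", {
  X <- data.frame(a = c(1, 2, NA, 4), b = c(TRUE, TRUE, FALSE, NA),
                  c = 1:4)
  out <- impute_rough(X)
  expect_equal(out$a[3], 2)      # median of {1,2,4}
  expect_true(out$b[4])          # mode of {T,T,F}
  expect_identical(out$c, X$c)   # no missing: identity
  expect_equal(sum(attr(out, "missing_mask")), 2)
  expect_error(impute_rough(data.frame(a = c(NA_real_, NA_real_))),
               "fully missing")
})

test_that("forest predictions agree with an independent implementation", {
  skip_if_not_installed("randomForest")
  set.seed(39)
  n <- 150
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 2 * X$x1 - X$x2^2 + rnorm(n, 0, 0.2)
  ours <- fit_forest(X, y, n_trees = 500, mtry = 2, seed = 16)
  ref <- randomForest::randomForest(X, y, ntree = 500, mtry = 2)
  expect_gt(cor(predict(ours, X), predict(ref, X)), 0.97)
  expect_lt(abs(ours$oob_mse - mean((y - ref$predicted)^2)) /
              mean((y - ref$predicted)^2), 0.35)
})
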