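#' Rough imputation of missing predictor values
#'
#' Numeric columns get the column median of observed values; logical columns
#' get the modal level. The missingness mask is retained in attribute
#' `"missing_mask"` for reporting.
#'
#' @param X Data frame of predictors (numeric and logical columns).
#' @return `X` with no missing values.
#' @export
impute_rough <- function(X) {
  mask <- is.na(as.data.frame(X))
  for (j in seq_along(X)) {
    nas <- is.na(X[[j]])
    if (!any(nas)) next
    if (all(nas)) stop(sprintf("column '%s' is fully missing", names(X)[j]))
    if (is.logical(X[[j]])) {
      X[[j]][nas] <- mean(X[[j]][!nas]) >= 0.5  # modal level
    } else {
      X[[j]][nas] <- stats::median(X[[j]][!nas])
    }
  }
  attr(X, "missing_mask") <- mask
  X
}

# coerce a predictor data frame to the numeric matrix the engine uses;
# logicals become 0/1, factors become integer codes (ordered splits)
.design_matrix <- function(X) {
  df <- as.data.frame(X)
  df <- df[, !(names(df) %in% "stock_id"), drop = FALSE]
  m <- vapply(df, function(col) {
    if (is.logical(col)) as.numeric(col)
    else if (is.factor(col) || is.character(col)) as.numeric(factor(col))
    else as.numeric(col)
  }, numeric(nrow(df)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df))
  colnames(m) <- names(df)
  m
}

#' Grow a single regression tree
#'
#' CART-style recursive partitioning: at each node, `mtry` covariates are
#' sampled without replacement and the split with the greatest sum-of-squares
#' reduction of the response is taken, with numeric cutpoints at midpoints
#' between sorted distinct values. Ties are broken by lowest covariate index,
#' then smallest cutpoint. Recursion stops at `min_node_size` in-bag rows or
#' zero response variance.
#'
#' @param X Predictor data frame or numeric matrix.
#' @param y Numeric response, no missing values.
#' @param mtry Covariates sampled at each node (default all).
#' @param min_node_size Nodes at or below this size are not split.
#' @param inbag Row indices (with multiplicity) forming the training sample;
#'   default all rows once.
#' @return Matrix of nodes (columns `var`, `split`, `left`, `right`, `value`,
#'   `n`), class `stocktactics_tree`.
#' @export
build_tree <- function(X, y, mtry = NULL, min_node_size = 5L,
                       inbag = seq_along(y)) {
  Xm <- .design_matrix(X)
  stopifnot(!anyNA(y), nrow(Xm) == length(y))
  if (is.null(mtry)) mtry <- ncol(Xm)
  if (mtry > ncol(Xm)) stop("mtry exceeds the number of predictors")
  tree <- .grow_tree_cpp(Xm, as.numeric(y), as.integer(inbag),
                         as.integer(mtry), as.integer(min_node_size))
  attr(tree, "predictors") <- colnames(Xm)
  class(tree) <- c("stocktactics_tree", class(tree))
  tree
}

#' Predict from a single regression tree
#' @param object A tree from [build_tree()].
#' @param newdata Predictor data frame or matrix.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.stocktactics_tree <- function(object, newdata, ...) {
  Xm <- .design_matrix(newdata)
  .predict_forest_cpp(list(unclass(object)), Xm)
}

#' Fit a bagged regression-tree ensemble
#'
#' Each tree is grown on an n-out-of-n bootstrap resample (stocks weighted
#' equally), sampling `mtry` covariates at each node. Out-of-bag predictions
#' for a stock average only the trees whose bootstrap sample omitted it. The
#' whole fit is bit-reproducible under a single `set.seed()`.
#'
#' @param X Predictor data frame (numeric/logical columns) or matrix.
#' @param y Numeric response, complete.
#' @param n_trees Number of trees (default 10000, as used for small
#'   stock-level datasets; reduce for simulation studies).
#' @param mtry Covariates sampled per node (default 5).
#' @param min_node_size Terminal node size (default 5, the usual regression
#'   default).
#' @param seed Optional integer seed applied before growing.
#' @return Object of class `bagged_forest` with elements `trees`, `inbag`
#'   (n x n_trees bootstrap counts), `oob_pred`, `oob_mse`, `predictors`,
#'   `y`, and the hyperparameters.
#' @export
fit_forest <- function(X, y, n_trees = 10000L, mtry = 5L, min_node_size = 5L,
                       seed = NULL) {
  Xm <- .design_matrix(X)
  y <- as.numeric(y)
  stopifnot(!anyNA(y), nrow(Xm) == length(y))
  if (anyNA(Xm)) stop("X has missing values; impute first (impute_rough)")
  if (mtry > ncol(Xm)) stop("mtry exceeds the number of predictors")
  if (!is.null(seed)) set.seed(seed)

  fit <- .grow_forest_cpp(Xm, y, as.integer(n_trees), as.integer(mtry),
                          as.integer(min_node_size))
  oob <- .oob_predict_cpp(fit$trees, fit$inbag, Xm)
  ok <- !is.na(oob)
  if (!all(ok)) {
    warning(sprintf("%d stock(s) never out of bag; excluded from OOB error",
                    sum(!ok)))
  }
  structure(list(
    trees = fit$trees, inbag = fit$inbag,
    oob_pred = oob, oob_mse = mean((y[ok] - oob[ok])^2),
    predictors = colnames(Xm), X = Xm, y = y,
    n_trees = as.integer(n_trees), mtry = as.integer(mtry),
    min_node_size = as.integer(min_node_size)
  ), class = "bagged_forest")
}

#' @export
print.bagged_forest <- function(x, ...) {
  cat(sprintf("Bagged regression-tree ensemble: %d trees, mtry = %d, n = %d, p = %d\n",
              x$n_trees, x$mtry, length(x$y), length(x$predictors)))
  cat(sprintf("  OOB MSE = %.6g (var(y) = %.6g)\n", x$oob_mse,
              stats::var(x$y)))
  invisible(x)
}

#' Predict from a bagged forest
#' @param object A [fit_forest()] model.
#' @param newdata Predictor data frame or matrix with the same columns.
#' @param ... Unused.
#' @return Numeric predictions (average over all trees).
#' @export
predict.bagged_forest <- function(object, newdata, ...) {
  Xm <- .design_matrix(newdata)
  Xm <- Xm[, object$predictors, drop = FALSE]
  .predict_forest_cpp(object$trees, Xm)
}

#' Out-of-bag mean squared error
#'
#' Cross-validation prediction accuracy: the mean squared residual of the
#' out-of-bag predictions. Stocks never out of bag (vanishingly rare at large
#' forests) are excluded with a warning at fit time.
#'
#' @param model A [fit_forest()] model.
#' @param y Response (defaults to the training response).
#' @return Scalar MSE.
#' @export
oob_mse <- function(model, y = model$y) {
  ok <- !is.na(model$oob_pred)
  mean((y[ok] - model$oob_pred[ok])^2)
}

#' Out-of-bag permutation importance
#'
#' The loss of prediction accuracy from removing each predictor: per tree,
#' the increase in out-of-bag MSE after permuting that predictor's values
#' among the tree's out-of-bag stocks, averaged over trees. Predictors
#' carrying no signal score approximately zero (positive or negative).
#'
#' @param model A [fit_forest()] model.
#' @param seed Optional seed for the permutations.
#' @return Data frame with `predictor`, `importance` (mean OOB MSE increase),
#'   `se` (Monte Carlo standard error over trees), sorted by importance.
#' @export
permutation_importance <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- .perm_importance_cpp(model$trees, model$inbag, model$X, model$y)
  out <- data.frame(predictor = model$predictors,
                    importance = res$importance, se = res$se,
                    stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Partial dependence of the forest prediction on one covariate
#'
#' For each grid value `g`, the covariate is forced to `g` for every stock
#' and the predictions are averaged (the marginal effect after accounting for
#' the average effects of the other predictors). Per-group curves (e.g.
#' region x taxa) average over the subgroup's rows only. Decile marks and the
#' middle-80% band of the covariate are attached for plotting.
#'
#' @param model A [fit_forest()] model.
#' @param covariate Predictor name.
#' @param grid Grid values; default 51 equally spaced points within the
#'   observed range (two levels for 0/1 covariates). Values outside the
#'   observed range are truncated with a warning.
#' @param groups Optional factor (length n) defining subgroups.
#' @return Object of class `partial_dependence`: data frame `curve`
#'   (`grid`, `yhat`, one column per group), plus attributes `deciles` and
#'   `band80`.
#' @export
partial_dependence <- function(model, covariate, grid = NULL, groups = NULL) {
  j <- match(covariate, model$predictors)
  if (is.na(j)) stop(sprintf("unknown covariate '%s'", covariate))
  x <- model$X[, j]
  rng <- range(x)
  if (is.null(grid)) {
    vals <- unique(x)
    grid <- if (length(vals) <= 2L) sort(vals)
            else seq(rng[1L], rng[2L], length.out = 51L)
  } else {
    if (any(grid < rng[1L] | grid > rng[2L])) {
      warning("grid values outside the observed range were truncated")
      grid <- pmin(pmax(grid, rng[1L]), rng[2L])
    }
    grid <- sort(unique(grid))
  }

  glev <- if (is.null(groups)) character(0) else levels(factor(groups))
  curve <- data.frame(grid = grid, yhat = NA_real_)
  for (g in glev) curve[[paste0("yhat_", g)]] <- NA_real_

  Xg <- model$X
  for (k in seq_along(grid)) {
    Xg[, j] <- grid[k]
    pred <- .predict_forest_cpp(model$trees, Xg)
    curve$yhat[k] <- mean(pred)
    for (g in glev) {
      curve[[paste0("yhat_", g)]][k] <- mean(pred[factor(groups) == g])
    }
  }
  structure(curve,
            covariate = covariate,
            deciles = stats::quantile(x, probs = seq(0.1, 0.9, by = 0.1)),
            band80 = stats::quantile(x, probs = c(0.1, 0.9)),
            class = c("partial_dependence", "data.frame"))
}

#' Marginal means of a two-level covariate, with the relative difference
#'
#' The level means are the partial-dependence values of the forest at the two
#' levels. The relative difference (`pct_diff`) is the absolute difference in
#' means expressed as a percentage of the span of the central 95% interval
#' (2.5-97.5 percentiles) of the observed response values across stocks.
#'
#' @param model A [fit_forest()] model.
#' @param covariate Name of a two-level (0/1 or logical) predictor.
#' @param y Observed responses used for the 95% span (default the training
#'   response).
#' @return List with `mean_level0`, `mean_level1`, `pct_diff`, `span95`.
#' @export
marginal_means <- function(model, covariate, y = model$y) {
  j <- match(covariate, model$predictors)
  if (is.na(j)) stop(sprintf("unknown covariate '%s'", covariate))
  lev <- sort(unique(model$X[, j]))
  if (length(lev) != 2L) stop("marginal_means() requires a two-level covariate")
  pd <- partial_dependence(model, covariate, grid = lev)
  q <- stats::quantile(y, probs = c(0.025, 0.975), na.rm = TRUE)
  span <- as.numeric(diff(q))
  m0 <- pd$yhat[1L]; m1 <- pd$yhat[2L]
  d <- abs(m1 - m0)
  list(mean_level0 = m0, mean_level1 = m1,
       pct_diff = if (d == 0) 0 else 100 * d / span, span95 = span)
}

#' Out-of-bag error over a range of mtry values
#'
#' Refits the forest at each candidate `mtry` and reports the OOB MSE, along
#' with the rule-of-thumb anchors p/3 (continuous predictors) and sqrt(p)
#' (categorical predictors) used to judge a reasonable choice.
#'
#' @param X,y Predictors and response as in [fit_forest()].
#' @param mtry_values Candidate values (subset of 1..p).
#' @param n_trees Trees per candidate fit.
#' @param seed Seed applied before each fit for comparability.
#' @return List with `table` (data frame `mtry`, `oob_mse`) and `anchors`
#'   (`p_over_3`, `sqrt_p`).
#' @export
mtry_diagnostic <- function(X, y, mtry_values = NULL, n_trees = 1000L,
                            seed = 1L) {
  Xm <- .design_matrix(X)
  p <- ncol(Xm)
  if (is.null(mtry_values)) mtry_values <- seq_len(p)
  stopifnot(all(mtry_values >= 1L), all(mtry_values <= p))
  mse <- vapply(mtry_values, function(m) {
    fit_forest(Xm, y, n_trees = n_trees, mtry = m, seed = seed)$oob_mse
  }, numeric(1))
  list(table = data.frame(mtry = mtry_values, oob_mse = mse),
       anchors = c(p_over_3 = round(p / 3, 2), sqrt_p = round(sqrt(p), 2)))
}
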