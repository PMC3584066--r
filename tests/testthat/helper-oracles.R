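# Exhaustive brute-force best-SSE split over all (variable, cutpoint) pairs,
# with the same tie-break as the engine: lowest covariate index, then smallest
# cutpoint. Independent of the C++ path.
brute_force_split <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  base <- sum(y)^2 / n
  best <- list(gain = 0, var = NA_integer_, split = NA_real_)
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2L) next
    for (k in seq_len(length(xs) - 1L)) {
      cut <- (xs[k] + xs[k + 1L]) / 2
      left <- X[, j] <= cut
      nl <- sum(left); nr <- n - nl
      gain <- sum(y[left])^2 / nl + sum(y[!left])^2 / nr - base
      if (gain > best$gain) best <- list(gain = gain, var = j, split = cut)
    }
  }
  best
}

# Exhaustive CART grown with the brute-force splitter (no covariate
# subsampling); returns predictions for the training rows.
brute_force_cart_predict <- function(X, y, min_node_size = 5L) {
  X <- as.matrix(X)
  pred <- numeric(length(y))
  recurse <- function(rows) {
    yy <- y[rows]
    if (length(rows) <= min_node_size || length(unique(yy)) == 1L) {
      pred[rows] <<- mean(yy)
      return(invisible())
    }
    bs <- brute_force_split(X[rows, , drop = FALSE], yy)
    if (is.na(bs$var)) {
      pred[rows] <<- mean(yy)
      return(invisible())
    }
    left <- X[rows, bs$var] <= bs$split
    recurse(rows[left])
    recurse(rows[!left])
  }
  recurse(seq_along(y))
  pred
}

# small fully-specified stock table for performance-module tests
make_stock_row <- function(stock_id = "S1", region = "Alaska", taxa = FALSE,
                           b_target = 400, f_target = 0.1,
                           last_data_year = 2010L,
                           low_commercial_value = FALSE,
                           rebuilding_in_window = FALSE,
                           co_caught_with_rebuilding = FALSE,
                           secondary_target = FALSE,
                           pct_recreational = 0) {
  data.frame(stock_id = stock_id, region = region, taxa = taxa,
             b_target = b_target, f_target = f_target,
             last_data_year = last_data_year,
             low_commercial_value = low_commercial_value,
             rebuilding_in_window = rebuilding_in_window,
             co_caught_with_rebuilding = co_caught_with_rebuilding,
             secondary_target = secondary_target,
             pct_recreational = pct_recreational,
             stringsAsFactors = FALSE)
}
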