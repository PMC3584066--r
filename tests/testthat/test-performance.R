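test_that("window selection takes the latest complete run and steps back past changes", {
  expect_equal(select_window(1990:2010), 2006:2010)
  expect_equal(select_window(1990:2010, change_years = 2008), 2003:2007)
  expect_equal(select_window(setdiff(1990:2010, 2009)), 2004:2008)
  # change at the window start also forces stepping back
  expect_equal(select_window(1990:2010, change_years = 2006), 2001:2005)
  w <- select_window(2007:2010)
  expect_length(w, 0)
  expect_match(attr(w, "reason"), "consecutive years")
})

test_that("stock filtering assigns one primary reason in priority order", {
  stocks <- rbind(
    make_stock_row("pre2000", last_data_year = 1998L),
    make_stock_row("lowval", low_commercial_value = TRUE),
    make_stock_row("rebuild", rebuilding_in_window = TRUE),
    make_stock_row("cocaught", co_caught_with_rebuilding = TRUE),
    make_stock_row("both", last_data_year = 1998L, rebuilding_in_window = TRUE),
    make_stock_row("clean"))
  res <- filter_stocks(stocks)
  expect_identical(res$included$stock_id, "clean")
  reasons <- setNames(res$excluded$reason, res$excluded$stock_id)
  expect_match(reasons[["pre2000"]], "prior to 2000")
  expect_match(reasons[["lowval"]], "commercial value")
  expect_match(reasons[["rebuild"]], "rebuilding plan")
  expect_match(reasons[["cocaught"]], "co-caught")
  expect_match(reasons[["both"]], "prior to 2000")  # primary reason only
})

test_that("catch components are matched to the TAC scope", {
  comp <- data.frame(year = c(2001, 2001, 2002, 2002, 2003, 2003),
                     component = rep(c("trawl", "fixed"), 3),
                     catch = c(80, 20, 70, 30, 60, 40))
  tac <- data.frame(year = c(2001, 2002), tac = c(100, 110),
                    scope = c("trawl", "all"))
  out <- screen_catch_tac(comp, tac)
  expect_equal(out$catch[out$year == 2001], 80)   # trawl only
  expect_equal(out$catch[out$year == 2002], 100)  # identity pass-through
  dropped <- attr(out, "dropped")
  expect_true(2003 %in% dropped$year)              # no TAC that year
  # zero TAC with positive catch is flagged out
  tac0 <- data.frame(year = 2001, tac = 0, scope = "all")
  out0 <- screen_catch_tac(comp[comp$year == 2001, ], tac0)
  expect_equal(nrow(out0), 0)
  expect_match(attr(out0, "dropped")$reason, "zero TAC")
})

test_that("log-ratio mean and sd match direct computation", {
  m <- snapshot_metrics(rep(1, 5), 1)
  expect_equal(c(m$mean, m$sd), c(0, 0))
  m <- snapshot_metrics(rep(exp(1), 5), 1)
  expect_equal(c(m$mean, m$sd), c(1, 0))
  x <- c(1.2, 0.8, 1.0, 1.1, 0.9)
  m <- snapshot_metrics(x, 1)
  expect_equal(m$mean, mean(log(x)))
  expect_equal(m$sd, sd(log(x)))
  # frozen from direct arithmetic on the five log ratios
  expect_equal(m$mean, -0.01017447, tolerance = 1e-6)
  expect_equal(m$sd, 0.16023535, tolerance = 1e-6)
  # invariance to common rescaling of values and target
  m2 <- snapshot_metrics(x * 37.5, 37.5)
  expect_equal(c(m2$mean, m2$sd), c(m$mean, m$sd))
})

test_that("semi-deviation matches hand-computed worked cases", {
  x <- c(1.1, 0.9, 1.35, 1.0, 0.8)
  # upper side: only 1.1 and 1.35 exceed the target
  expect_equal(semideviation(x, 1, "upper"),
               sqrt((log(1.1)^2 + log(1.35)^2) / 5), tolerance = 1e-12)
  expect_equal(semideviation(x, 1, "upper"), 0.1408168, tolerance = 1e-6)
  # lower side: only 0.9 and 0.8 fall below
  expect_equal(semideviation(x, 1, "lower"),
               sqrt((log(0.9)^2 + log(0.8)^2) / 5), tolerance = 1e-12)
  expect_equal(semideviation(x, 1, "lower"), 0.1103575, tolerance = 1e-6)
})

test_that("semi-deviation is zero iff no undesirable excursion, and monotone", {
  expect_identical(semideviation(c(0.5, 0.9, 1.0, 0.7, 0.2), 1, "upper"), 0)
  expect_identical(semideviation(c(1.5, 1.9, 1.0, 1.7, 1.2), 1, "lower"), 0)
  base <- semideviation(c(1.1, 0.9, 1.35, 1.0, 0.8), 1, "upper")
  worse <- semideviation(c(1.1, 0.9, 1.50, 1.0, 0.8), 1, "upper")
  expect_gt(worse, base)
  expect_error(semideviation(c(1, -1, 1, 1, 1), 1, "upper"), "positive")
})

test_that("semi-deviation log-symmetry identity holds on random windows", {
  set.seed(101)
  for (i in 1:1000) {
    x <- exp(rnorm(5, 0, 0.5))
    tg <- exp(rnorm(1, 0, 0.3))
    expect_equal(semideviation(x, tg, "upper"),
                 semideviation(1 / x, 1 / tg, "lower"), tolerance = 1e-12)
  }
})

test_that("mean-absolute semi-deviation variant is available", {
  x <- c(1.1, 0.9, 1.35, 1.0, 0.8)
  expect_equal(semideviation(x, 1, "upper", method = "mean_abs"),
               (log(1.1) + log(1.35)) / 5)
})

test_that("pooled discard proportion is catch-weighted and bounded", {
  expect_equal(discard_proportion(rep(1, 5), rep(10, 5)), 0.1)
  expect_equal(discard_proportion(rep(0, 5), rep(10, 5)), 0)
  expect_equal(discard_proportion(c(2, 0, 4, 0, 4), c(10, 10, 20, 10, 50)), 0.1)
  expect_true(is.na(discard_proportion(rep(0, 3), rep(0, 3))))
  set.seed(3)
  for (i in 1:50) {
    catch <- runif(5, 1, 100)
    disc <- catch * runif(5)
    pooled <- discard_proportion(disc, catch)
    annual <- disc / catch
    expect_gte(pooled, min(annual))
    expect_lte(pooled, max(annual))
  }
})

test_that("year of development is the first year at 25% of peak landings", {
  expect_equal(year_of_development(c(10, 20, 30, 100, 80), 1:5), 3)
  expect_equal(year_of_development(rep(5, 4), 1:4), 1)
  expect_equal(year_of_development(c(100, 10, 10), 1:3), 1)
  expect_error(year_of_development(rep(0, 5)), "all-zero")
})

test_that("performance table computes all ten measures per stock", {
  set.seed(8)
  fl <- generate_fleet(fleet_config(n_stocks = 12, seed = 21))
  res <- performance_table(fl$annual, fl$stocks)
  expect_setequal(
    setdiff(performance_measures(), names(res$performance)), character(0))
  expect_equal(nrow(res$performance) + nrow(res$excluded), 12)
  expect_true(all(res$performance$sd_catch_tac >= 0, na.rm = TRUE))
  expect_true(all(res$performance$semidev_b >= 0, na.rm = TRUE))
  expect_true(all(res$performance$discard_prop >= 0 &
                    res$performance$discard_prop <= 1, na.rm = TRUE))
  expect_identical(unname(res$n_per_metric["mean_catch_tac"]),
                   sum(is.finite(res$performance$mean_catch_tac)))
})
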