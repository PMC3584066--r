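noiseless <- function(...) {
  simulate_stock(..., process_sd = 0, implementation_sd = 0,
                 assessment_sd = 0, ramp_years = 0L)
}

test_that("unfished stock at carrying capacity stays there", {
  sim <- noiseless(r = 0.4, K = 1000, n_years = 20, f_target = 0,
                   b0_frac = 1, mu_impl = 0)
  expect_equal(sim$annual$biomass, rep(1000, 20))
  expect_equal(sim$annual$catch, rep(0, 20))
  expect_false(sim$collapsed)
})

test_that("fishing at F_MSY from B_MSY holds the MSY equilibrium", {
  sim <- noiseless(r = 0.4, K = 1000, n_years = 20, f_target = 0.2,
                   b_full = 0.4, b0_frac = 0.5, mu_impl = 0)
  expect_equal(sim$annual$biomass, rep(500, 20))
  expect_equal(sim$annual$catch, rep(100, 20))  # MSY = rK/4
  expect_equal(sim$annual$F, rep(0.2, 20))
})

test_that("simulation is bit-identical under a fixed seed", {
  run <- function() {
    set.seed(99)
    simulate_stock(r = 0.3, K = 800, n_years = 25, process_sd = 0.1)
  }
  expect_identical(run(), run())
})

test_that("persistent overharvest flags collapse without erroring", {
  # control rule effectively disabled: full target F at any biomass
  sim <- noiseless(r = 0.1, K = 1000, n_years = 40, f_target = 0.95,
                   b_full = 1e-9, b_lim = 0, b0_frac = 0.3, mu_impl = 0)
  expect_true(sim$collapsed)
  expect_true(all(sim$annual$biomass > 0))
})

test_that("invalid rates are rejected", {
  expect_error(simulate_stock(r = 2.5, K = 1000, n_years = 20), "r must be")
  expect_error(simulate_stock(r = 0.3, K = -1, n_years = 20), "K must be")
  expect_error(simulate_stock(r = 0.3, K = 1000, n_years = 5), "n_years")
})

test_that("landings plus discards equal total catch in every year", {
  fl <- generate_fleet(fleet_config(n_stocks = 20, seed = 31))
  expect_equal(fl$annual$landings + fl$annual$discards, fl$annual$catch)
})

test_that("fleet generation is deterministic under the config seed", {
  a <- generate_fleet(fleet_config(n_stocks = 15, seed = 7))
  b <- generate_fleet(fleet_config(n_stocks = 15, seed = 7))
  expect_identical(a, b)
})

test_that("zero effects and zero noise give exactly the configured bias", {
  cfg <- fleet_config(n_stocks = 10, effect_table = list(),
                      process_sd = 0, implementation_sd = 0,
                      assessment_sd = 0, mu_catch_tac = log(0.7), seed = 5)
  fl <- generate_fleet(cfg)
  res <- performance_table(fl$annual, fl$stocks)
  expect_equal(res$performance$mean_catch_tac,
               rep(log(0.7), nrow(res$performance)))
  expect_equal(res$performance$sd_catch_tac,
               rep(0, nrow(res$performance)))
  # all catches at/below TAC: no upper-side excursion
  expect_equal(res$performance$semidev_catch_tac,
               rep(0, nrow(res$performance)))
})

test_that("an injected price effect on discards yields a negative association", {
  cfg <- fleet_config(
    n_stocks = 80,
    effect_table = list(list(covariate = "exvessel_price",
                             metric = "discard_prop",
                             direction = -1, magnitude = 1.5)),
    seed = 13)
  fl <- generate_fleet(cfg)
  res <- performance_table(fl$annual, fl$stocks)
  d <- merge(res$performance, fl$covariates, by = "stock_id")
  rho <- cor(d$exvessel_price, d$discard_prop, method = "spearman",
             use = "complete.obs")
  expect_lt(rho, -0.5)
})

test_that("with no injected effect, covariate-metric associations vanish", {
  cfg <- fleet_config(n_stocks = 200, effect_table = list(), seed = 17)
  fl <- generate_fleet(cfg)
  res <- performance_table(fl$annual, fl$stocks)
  d <- merge(res$performance, fl$covariates, by = "stock_id")
  for (cov in c("pct_mpa", "pct_bycatch_constrained", "pct_bottom_trawl")) {
    for (metric in c("mean_catch_tac", "discard_prop", "mean_b")) {
      expect_lt(abs(cor(d[[cov]], d[[metric]], use = "complete.obs")), 0.2)
    }
  }
})

test_that("inconsistent effect tables are rejected", {
  expect_error(fleet_config(effect_table = list(
    list(covariate = "exvessel_price", metric = "no_such_metric",
         direction = 1, magnitude = 0.2))), "not supported")
  expect_error(fleet_config(effect_table = list(
    list(covariate = "no_such_covariate", metric = "mean_catch_tac",
         direction = 1, magnitude = 0.2))), "unknown")
  expect_error(fleet_config(effect_table = list(
    list(covariate = "pct_iq", metric = "sd_catch_tac",
         direction = -1, magnitude = Inf))), "finite")
})

test_that("every stock has exactly one ground-truth entry, and files round-trip", {
  fl <- generate_fleet(fleet_config(n_stocks = 12, seed = 3))
  expect_identical(sort(fl$ground_truth$stocks$stock_id),
                   sort(fl$stocks$stock_id))
  expect_equal(anyDuplicated(fl$ground_truth$stocks$stock_id), 0L)
  dir <- file.path(tempdir(), "fleet_out")
  write_fleet(fl, dir)
  ann <- read.csv(file.path(dir, "annual.csv"))
  expect_equal(nrow(ann), nrow(fl$annual))
  expect_setequal(names(ann), names(fl$annual))
  cov <- read.csv(file.path(dir, "covariates.csv"))
  expect_equal(cov$exvessel_price, fl$covariates$exvessel_price)
})
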