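#' Default per-region covariate distributions for the synthetic fleet
#'
#' Region-specific generating parameters for the management covariates,
#' shaped to mimic the broad contrasts reported for western North American
#' groundfish: near-universal individual quotas and seasonal closures in
#' British Columbia, roughly tenfold larger catches and lower ex-vessel
#' prices in Alaska, later fishery development in Alaska, more spatial
#' closure on the U.S. West Coast for some stocks, and harvest control rules
#' with limit reference points common in the two U.S. regions.
#'
#' @return Named list (one element per region) of distribution parameters.
#' @export
default_covariate_distributions <- function() {
  list(
    Alaska = list(
      pct_mpa = c(3, 17), pct_bycatch = c(1.5, 15),
      iq = list(p_any = 0.2, shape = c(2, 2)),
      pct_bottom_trawl = c(6, 2),
      log_price = c(log(800), 0.5), log_K = c(log(2e5), 1.0),
      start_year = c(1965, 1980),
      hcr_p = 0.8, seasonal_p = 0.5, rockfish_p = 0.35
    ),
    BC = list(
      pct_mpa = c(3, 17), pct_bycatch = c(4, 16),
      iq = list(p_any = 0.95, shape = c(40, 2)),
      pct_bottom_trawl = c(5, 2.2),
      log_price = c(log(1500), 0.5), log_K = c(log(2e4), 1.0),
      start_year = c(1950, 1968),
      hcr_p = 0.3, seasonal_p = 0.95, rockfish_p = 0.35
    ),
    USWC = list(
      pct_mpa = c(1.5, 18), pct_bycatch = c(1.5, 15),
      iq = list(p_any = 0.1, shape = c(2, 2)),
      pct_bottom_trawl = c(3.5, 2.4),
      log_price = c(log(2500), 0.5), log_K = c(log(2e4), 1.0),
      start_year = c(1950, 1968),
      hcr_p = 0.8, seasonal_p = 0.5, rockfish_p = 0.35
    )
  )
}

#' Default injected covariate effects
#'
#' The generator's ground-truth effects, mimicking the dominant associations
#' reported for groundfish fleets: higher-priced stocks are kept closer to
#' their TAC and are discarded less, and catch-share (IQ) coverage reduces
#' the interannual variability of catch relative to TAC (implementation
#' error). Magnitudes are on the log scale per standard deviation of the
#' (z-scored) covariate.
#'
#' @return List of effects, each `list(covariate, metric, direction,
#'   magnitude)`.
#' @export
default_effect_table <- function() {
  list(
    list(covariate = "exvessel_price", metric = "mean_catch_tac",
         direction = +1, magnitude = 0.3),
    list(covariate = "exvessel_price", metric = "discard_prop",
         direction = -1, magnitude = 1.5),
    list(covariate = "pct_iq", metric = "sd_catch_tac",
         direction = -1, magnitude = 1.1)
  )
}

#' Configuration for a synthetic multi-stock fleet
#'
#' @param n_stocks Number of stocks (>= 2); default 85.
#' @param regions Named numeric vector of region proportions summing to 1.
#' @param covariate_distributions Per-region generating parameters; see
#'   [default_covariate_distributions()].
#' @param effect_table Injected covariate effects; see
#'   [default_effect_table()]. Supported metrics: `mean_catch_tac`,
#'   `sd_catch_tac`, `discard_prop`.
#' @param process_sd Lognormal process-noise SD on annual biomass.
#' @param implementation_sd Baseline lognormal SD of catch about the TAC.
#' @param assessment_sd Lognormal SD of the biomass estimate used to set the
#'   TAC.
#' @param mu_catch_tac Baseline mean of `ln(catch/TAC)` (implementation bias;
#'   fisheries typically land less than the TAC, so this is negative).
#' @param discard_base Baseline discard fraction at the reference price.
#' @param f_target_mult Management F target as a multiple of F_MSY (targets
#'   are typically more conservative than MSY).
#' @param b_target_frac Management B target as a fraction of K (a B40%-style
#'   proxy).
#' @param final_year Last simulated year for every stock.
#' @param flag_rates Rates of administrative flags (low commercial value,
#'   rebuilding, co-caught with rebuilding, secondary target).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return Object of class `fleet_config`.
#' @export
fleet_config <- function(n_stocks = 85L,
                         regions = c(Alaska = 0.36, BC = 0.40, USWC = 0.24),
                         covariate_distributions = default_covariate_distributions(),
                         effect_table = default_effect_table(),
                         process_sd = 0.10,
                         implementation_sd = 0.15,
                         assessment_sd = 0.15,
                         mu_catch_tac = log(0.65),
                         discard_base = 0.15,
                         f_target_mult = 0.75,
                         b_target_frac = 0.40,
                         final_year = 2010L,
                         flag_rates = c(low_value = 0.05, rebuilding = 0.05,
                                        co_caught = 0.05, secondary = 0.10),
                         seed = NULL) {
  stopifnot(n_stocks >= 2L, abs(sum(regions) - 1) < 1e-8,
            process_sd >= 0, implementation_sd >= 0,
            all(names(regions) %in% names(covariate_distributions)))
  supported <- c("mean_catch_tac", "sd_catch_tac", "discard_prop")
  known_cov <- c("hcr_limit_rp", "seasonal_closures", "taxa", "pct_mpa",
                 "pct_bycatch_constrained", "pct_iq", "pct_bottom_trawl",
                 "total_catch", "exvessel_price", "year_dev", "age_maturity")
  for (e in effect_table) {
    if (!is.finite(e$magnitude)) stop("effect magnitudes must be finite")
    if (!e$metric %in% supported) {
      stop(sprintf("effect_table metric '%s' not supported (use one of %s)",
                   e$metric, paste(supported, collapse = ", ")))
    }
    if (!e$covariate %in% known_cov) {
      stop(sprintf("effect_table covariate '%s' unknown", e$covariate))
    }
  }
  structure(list(
    n_stocks = as.integer(n_stocks), regions = regions,
    covariate_distributions = covariate_distributions,
    effect_table = effect_table,
    process_sd = process_sd, implementation_sd = implementation_sd,
    assessment_sd = assessment_sd,
    mu_catch_tac = mu_catch_tac, discard_base = discard_base,
    f_target_mult = f_target_mult, b_target_frac = b_target_frac,
    final_year = as.integer(final_year), flag_rates = flag_rates,
    seed = seed
  ), class = "fleet_config")
}

#' Harvest control rule: 40-10-style linear ramp
#'
#' Returns the exploitation rate prescribed at biomass `B`: the full target F
#' at or above `b_full * K`, zero at or below `b_lim * K` (the limit
#' reference point below which directed fishing stops), linear in between.
#'
#' @param B Current biomass.
#' @param K Carrying capacity.
#' @param f_target Target exploitation rate applied at full stock size.
#' @param b_full,b_lim Ramp shoulders as fractions of K (defaults 0.4, 0.1).
#' @return Prescribed exploitation rate.
#' @export
hcr_ramp <- function(B, K, f_target, b_full = 0.4, b_lim = 0.1) {
  frac <- B / K
  scale <- pmin(1, pmax(0, (frac - b_lim) / (b_full - b_lim)))
  f_target * scale
}

#' Simulate one stock under Schaefer dynamics with a harvest control rule
#'
#' Biomass follows `B[t+1] = (B[t] + r*B[t]*(1 - B[t]/K) - C[t]) * e`, with
#' `e` a mean-one lognormal process deviate. The TAC is set each year by the
#' 40-10-style control rule from current biomass; realized catch is the TAC
#' times a mean-one lognormal implementation deviate and a bias factor
#' `exp(mu_impl)`, truncated below the current biomass. An effort ramp over
#' the first years of the fishery produces a development phase in landings.
#' The discard fraction decreases logistically with ex-vessel price.
#'
#' @param r,K Schaefer parameters (`0 < r < 2`, `K > 0`).
#' @param n_years Number of simulated years (>= 10).
#' @param f_target,b_full,b_lim Control-rule parameters (see [hcr_ramp()]).
#' @param process_sd,implementation_sd Lognormal noise SDs (bias-corrected so
#'   the deviates have mean 1).
#' @param assessment_sd Lognormal SD of the biomass estimate used to set the
#'   TAC (assessment error); the control rule sees the estimated, not the
#'   true, biomass.
#' @param mu_impl Mean of `ln(catch/TAC)` (implementation bias).
#' @param price Ex-vessel price, used by the discard model.
#' @param discard_params List: `base` fraction at the reference price,
#'   `slope` per SD of log price, `center`/`scale` of log price, `offset`
#'   added to the linear predictor (used for injected effects).
#' @param start_year First calendar year.
#' @param ramp_years Years over which fishing effort ramps up from zero.
#' @param b0_frac Initial depletion, `B[1] = b0_frac * K`.
#' @param tac_abc_ratio TAC as a fraction of the ABC.
#' @return List with `annual` (data frame: `year`, `biomass`, `F`, `catch`,
#'   `tac`, `abc`, `discards`, `landings`) and `collapsed` flag (`TRUE` if
#'   biomass hit the collapse floor; the series is still returned).
#' @export
simulate_stock <- function(r, K, n_years,
                           f_target = 0.75 * r / 2,
                           b_full = 0.4, b_lim = 0.1,
                           process_sd = 0.1, implementation_sd = 0.15,
                           assessment_sd = 0.15,
                           mu_impl = log(0.65),
                           price = 1500,
                           discard_params = list(base = 0.15, slope = 1.5,
                                                 center = log(1500),
                                                 scale = 0.7, offset = 0),
                           start_year = 1971L, ramp_years = 8L,
                           b0_frac = 0.6, tac_abc_ratio = 0.9) {
  if (!(r > 0 && r < 2)) stop("r must be in (0, 2)")
  if (K <= 0) stop("K must be positive")
  if (n_years < 10L) stop("n_years must be >= 10")
  stopifnot(process_sd >= 0, implementation_sd >= 0, assessment_sd >= 0)

  dfrac <- stats::plogis(
    stats::qlogis(discard_params$base) -
      discard_params$slope * (log(price) - discard_params$center) /
        discard_params$scale +
      discard_params$offset)

  floor_b <- K * 1e-4
  years <- seq.int(start_year, length.out = n_years)
  B <- numeric(n_years); C <- numeric(n_years); tac <- numeric(n_years)
  B[1L] <- b0_frac * K
  collapsed <- FALSE

  for (t in seq_len(n_years)) {
    B_est <- if (assessment_sd > 0) {
      B[t] * exp(stats::rnorm(1L, -assessment_sd^2 / 2, assessment_sd))
    } else B[t]
    tac[t] <- hcr_ramp(B_est, K, f_target, b_full, b_lim) * B_est
    ramp <- if (ramp_years > 0L) min(1, (t - 1L) / ramp_years) else 1
    dev_impl <- if (implementation_sd > 0) {
      exp(stats::rnorm(1L, -implementation_sd^2 / 2, implementation_sd))
    } else 1
    C[t] <- min(tac[t] * exp(mu_impl) * dev_impl * ramp, 0.9 * B[t])
    if (t < n_years) {
      dev_proc <- if (process_sd > 0) {
        exp(stats::rnorm(1L, -process_sd^2 / 2, process_sd))
      } else 1
      Bnext <- (B[t] + r * B[t] * (1 - B[t] / K) - C[t]) * dev_proc
      if (Bnext <= floor_b) {
        collapsed <- TRUE
        Bnext <- floor_b
      }
      B[t + 1L] <- Bnext
    }
  }

  discards <- dfrac * C
  list(
    annual = data.frame(
      year = years, biomass = B, F = ifelse(B > 0, C / B, NA_real_),
      catch = C, tac = tac, abc = tac / tac_abc_ratio,
      discards = discards, landings = C - discards),
    collapsed = collapsed,
    discard_fraction = dfrac
  )
}

# z-score with a guard for constant columns
.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a synthetic multi-stock fleet with recorded ground truth
#'
#' Draws stock-level covariates per region, simulates each stock's annual
#' series under Schaefer dynamics with a harvest control rule, injects the
#' configured covariate effects by shifting the generating parameters
#' (implementation bias, implementation SD, discard fraction), and records
#' every generating value in a ground-truth table. `total_catch` and
#' `year_dev` covariates are derived from the simulated series, as they would
#' be from real data.
#'
#' @param config A [fleet_config()].
#' @return List with `annual` (all stocks' annual records), `stocks`
#'   (stock-level table: region, taxa, targets, administrative flags),
#'   `covariates` (one row per stock: the 11 predictors plus `region` and
#'   `max_length` for sensitivity runs), and `ground_truth`.
#' @export
generate_fleet <- function(config) {
  stopifnot(inherits(config, "fleet_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_stocks
  region <- sample(names(config$regions), n, replace = TRUE,
                   prob = config$regions)
  cd <- config$covariate_distributions

  draw <- function(field) lapply(region, function(rg) cd[[rg]][[field]])
  rbeta2 <- function(par) stats::rbeta(1L, par[1L], par[2L])

  rockfish <- vapply(region, function(rg) stats::runif(1) < cd[[rg]]$rockfish_p,
                     logical(1))
  hcr <- vapply(region, function(rg) stats::runif(1) < cd[[rg]]$hcr_p, logical(1))
  seasonal <- vapply(region, function(rg) stats::runif(1) < cd[[rg]]$seasonal_p,
                     logical(1))
  pct_mpa <- vapply(draw("pct_mpa"), rbeta2, numeric(1))
  pct_byc <- vapply(draw("pct_bycatch"), rbeta2, numeric(1))
  pct_iq <- vapply(seq_len(n), function(i) {
    iq <- cd[[region[i]]]$iq
    if (stats::runif(1) < iq$p_any) stats::rbeta(1L, iq$shape[1L], iq$shape[2L])
    else 0
  }, numeric(1))
  pct_trawl <- vapply(draw("pct_bottom_trawl"), rbeta2, numeric(1))
  price <- vapply(seq_len(n), function(i) {
    p <- cd[[region[i]]]$log_price
    stats::rlnorm(1L, p[1L], p[2L])
  }, numeric(1))
  K <- vapply(seq_len(n), function(i) {
    p <- cd[[region[i]]]$log_K
    stats::rlnorm(1L, p[1L], p[2L])
  }, numeric(1))
  start_year <- vapply(seq_len(n), function(i) {
    p <- cd[[region[i]]]$start_year
    as.integer(round(stats::runif(1L, p[1L], p[2L])))
  }, integer(1))
  r <- ifelse(rockfish,
              pmin(pmax(stats::rlnorm(n, log(0.10), 0.3), 0.02), 1.5),
              pmin(pmax(stats::rlnorm(n, log(0.30), 0.3), 0.02), 1.5))
  age_mat <- ifelse(rockfish, stats::rlnorm(n, log(12), 0.25),
                    stats::rlnorm(n, log(6), 0.25))
  max_length <- ifelse(rockfish, stats::rlnorm(n, log(55), 0.25),
                       stats::rlnorm(n, log(80), 0.3))

  # injected effects act on z-scored covariates so magnitudes are comparable
  cov_raw <- list(pct_mpa = pct_mpa, pct_bycatch_constrained = pct_byc,
                  pct_iq = pct_iq, pct_bottom_trawl = pct_trawl,
                  exvessel_price = log(price), age_maturity = age_mat,
                  hcr_limit_rp = as.numeric(hcr),
                  seasonal_closures = as.numeric(seasonal),
                  taxa = as.numeric(rockfish))
  z <- lapply(cov_raw, .zscore)

  mu_impl <- rep(config$mu_catch_tac, n)
  log_imp_sd_mult <- rep(0, n)
  discard_offset <- rep(0, n)
  for (e in config$effect_table) {
    zc <- z[[e$covariate]]
    if (is.null(zc)) {
      stop(sprintf("effect covariate '%s' cannot be injected (derived)",
                   e$covariate))
    }
    shift <- e$direction * e$magnitude * zc
    if (e$metric == "mean_catch_tac") mu_impl <- mu_impl + shift
    if (e$metric == "sd_catch_tac") log_imp_sd_mult <- log_imp_sd_mult + shift
    if (e$metric == "discard_prop") discard_offset <- discard_offset + shift
  }
  imp_sd <- config$implementation_sd * exp(log_imp_sd_mult)

  stock_id <- sprintf("S%03d", seq_len(n))
  f_target <- config$f_target_mult * r / 2
  b_target <- config$b_target_frac * K

  annual <- vector("list", n)
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    ramp <- sample(3:15, 1L)
    sims[[i]] <- simulate_stock(
      r = r[i], K = K[i],
      n_years = config$final_year - start_year[i] + 1L,
      f_target = f_target[i],
      process_sd = config$process_sd, implementation_sd = imp_sd[i],
      assessment_sd = config$assessment_sd,
      mu_impl = mu_impl[i], price = price[i],
      discard_params = list(base = config$discard_base, slope = 0,
                            center = log(1500), scale = 0.7,
                            offset = discard_offset[i]),
      start_year = start_year[i], ramp_years = ramp)
    a <- sims[[i]]$annual
    a$stock_id <- stock_id[i]
    annual[[i]] <- a[, c("stock_id", setdiff(names(a), "stock_id"))]
  }
  annual <- do.call(rbind, annual)

  # covariates derived from the simulated series (last-5-year mean catch;
  # development year from the landings series)
  total_catch <- vapply(seq_len(n), function(i) {
    a <- sims[[i]]$annual
    mean(utils::tail(a$catch, 5L))
  }, numeric(1))
  year_dev <- vapply(seq_len(n), function(i) {
    a <- sims[[i]]$annual
    year_of_development(a$landings, a$year)
  }, numeric(1))

  fr <- config$flag_rates
  stocks <- data.frame(
    stock_id = stock_id, region = region, taxa = rockfish,
    b_target = b_target, f_target = f_target,
    last_data_year = config$final_year,
    low_commercial_value = stats::runif(n) < fr[["low_value"]],
    rebuilding_in_window = stats::runif(n) < fr[["rebuilding"]],
    co_caught_with_rebuilding = stats::runif(n) < fr[["co_caught"]],
    secondary_target = stats::runif(n) < fr[["secondary"]],
    pct_recreational = stats::rbeta(n, 0.5, 6),
    collapsed = vapply(sims, `[[`, logical(1), "collapsed"),
    stringsAsFactors = FALSE)

  covariates <- data.frame(
    stock_id = stock_id,
    hcr_limit_rp = hcr, seasonal_closures = seasonal, taxa = rockfish,
    pct_mpa = pct_mpa, pct_bycatch_constrained = pct_byc, pct_iq = pct_iq,
    pct_bottom_trawl = pct_trawl, total_catch = total_catch,
    exvessel_price = price, year_dev = year_dev, age_maturity = age_mat,
    region = region, max_length = max_length,
    stringsAsFactors = FALSE)

  ground_truth <- list(
    stocks = data.frame(
      stock_id = stock_id, r = r, K = K,
      f_target = f_target, b_target = b_target,
      mu_impl = mu_impl, implementation_sd = imp_sd,
      discard_fraction = vapply(sims, `[[`, numeric(1), "discard_fraction"),
      stringsAsFactors = FALSE),
    effect_table = config$effect_table,
    seed = config$seed)

  list(annual = annual, stocks = stocks, covariates = covariates,
       ground_truth = ground_truth)
}

#' Write a synthetic fleet to delimited files
#'
#' Writes `annual.csv` (stock_id, year, biomass, F, catch, tac, abc,
#' discards, landings), `covariates.csv`, `stocks.csv`, and
#' `ground_truth.csv` under `dir`.
#'
#' @param fleet Result of [generate_fleet()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fleet <- function(fleet, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fleet$annual, file.path(dir, "annual.csv"),
                   row.names = FALSE)
  utils::write.csv(fleet$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(fleet$stocks, file.path(dir, "stocks.csv"),
                   row.names = FALSE)
  utils::write.csv(fleet$ground_truth$stocks,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
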