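#' Names of the eleven key-run predictors
#' @return Character vector.
#' @export
key_predictors <- function() {
  c("hcr_limit_rp", "seasonal_closures", "taxa", "pct_mpa",
    "pct_bycatch_constrained", "pct_iq", "pct_bottom_trawl",
    "total_catch", "exvessel_price", "year_dev", "age_maturity")
}

# stable stage seed derived from the master seed and the stage name,
# kept below 2^31 so it is a valid R integer seed
.stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

#' Run configuration for the end-to-end analysis
#'
#' @param mode `"synthetic"` (simulate a fleet) or `"tables"` (read delimited
#'   tables from `input_dir` as written by [write_fleet()]).
#' @param fleet A [fleet_config()] (synthetic mode).
#' @param input_dir Directory of input tables (tables mode).
#' @param seed Master seed; stage seeds are derived by stable hashing of the
#'   master seed and stage name so stages can be rerun in isolation.
#' @param n_trees,mtry,min_node_size Forest hyperparameters.
#' @param scenario One of `"key"`, `"a"` (drop stocks with >50% recreational
#'   catch), `"b"` (drop stocks with window-mean catch:TAC < 0.5), `"c"`
#'   (drop secondary targets), `"d"` (add the 3-level region predictor),
#'   `"e"` (add maximum length as a predictor).
#' @param out_dir Optional output directory for delimited artifacts and plots.
#' @param responses Performance measures to attribute (default all ten).
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "tables"), fleet = fleet_config(),
                       input_dir = NULL, seed = 1L, n_trees = 10000L,
                       mtry = 5L, min_node_size = 5L,
                       scenario = c("key", "a", "b", "c", "d", "e"),
                       out_dir = NULL, responses = performance_measures()) {
  mode <- match.arg(mode)
  scenario <- match.arg(scenario)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (mode == "tables" && is.null(input_dir)) {
    stop("tables mode requires input_dir")
  }
  structure(list(mode = mode, fleet = fleet, input_dir = input_dir,
                 seed = as.integer(seed), n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry),
                 min_node_size = as.integer(min_node_size),
                 scenario = scenario, out_dir = out_dir,
                 responses = responses),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the optional
#' `fleet:` block mirrors the scalar arguments of [fleet_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fleet_args <- cfg$fleet %||% list()
  fleet <- do.call(fleet_config, fleet_args)
  args <- cfg[setdiff(names(cfg), "fleet")]
  args$fleet <- fleet
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a sensitivity scenario
#'
#' Scenario `key` is the identity; `a`-`c` drop stocks (recreational-dominated,
#' weakly targeted with window-mean catch:TAC below 0.5, secondary targets);
#' `d` and `e` keep all stocks and add a predictor (3-level region, maximum
#' length), giving p = 12.
#'
#' @param performance Performance table (one row per stock).
#' @param covariates Covariate table (must carry `region` and `max_length`
#'   for scenarios d and e).
#' @param stocks Stock-level table with `pct_recreational` and
#'   `secondary_target` flags.
#' @param scenario Scenario id.
#' @return List with filtered `performance`, `covariates`, and the
#'   `predictors` to use.
#' @export
apply_scenario <- function(performance, covariates, stocks,
                           scenario = c("key", "a", "b", "c", "d", "e")) {
  scenario <- match.arg(scenario)
  preds <- key_predictors()
  keep <- performance$stock_id
  if (scenario == "a") {
    rec <- stocks$pct_recreational[match(keep, stocks$stock_id)]
    keep <- keep[!(is.finite(rec) & rec > 0.5)]
  } else if (scenario == "b") {
    ct <- performance$mean_ratio_catch_tac
    keep <- keep[!(is.finite(ct) & ct < 0.5)]
  } else if (scenario == "c") {
    sec <- stocks$secondary_target[match(keep, stocks$stock_id)]
    keep <- keep[!(sec %in% TRUE)]
  } else if (scenario == "d") {
    preds <- c(preds, "region")
  } else if (scenario == "e") {
    preds <- c(preds, "max_length")
  }
  missing_preds <- setdiff(preds, names(covariates))
  if (length(missing_preds)) {
    stop("covariates lack fields required by the scenario: ",
         paste(missing_preds, collapse = ", "))
  }
  list(performance = performance[performance$stock_id %in% keep, , drop = FALSE],
       covariates = covariates[covariates$stock_id %in% keep, , drop = FALSE],
       predictors = preds)
}

#' Attribute one response to the management covariates
#'
#' Fits a bagged forest of the response on the predictors (stocks with a
#' missing response are dropped; missing predictor values are imputed), and
#' returns the fitted model with permutation importance, partial-dependence
#' curves for the numeric predictors, and marginal means for the two-level
#' predictors.
#'
#' @param performance Performance table.
#' @param covariates Covariate table (with `stock_id`).
#' @param response One of [performance_measures()].
#' @param predictors Predictor names (default the 11 key-run predictors).
#' @param n_trees,mtry,min_node_size,seed Forest settings.
#' @param pd_groups Optional grouping factor name in `covariates` for
#'   per-group partial-dependence curves (e.g. `"region"`); `NULL` for none.
#' @return List with `response`, `n`, `model`, `importance`, `pd` (named list
#'   of curves), `marginal_means` (named list).
#' @export
attribute_response <- function(performance, covariates, response,
                               predictors = key_predictors(),
                               n_trees = 10000L, mtry = 5L,
                               min_node_size = 5L, seed = NULL,
                               pd_groups = NULL) {
  y <- performance[[response]]
  ok <- is.finite(y)
  ids <- performance$stock_id[ok]
  X <- covariates[match(ids, covariates$stock_id), predictors, drop = FALSE]
  X <- impute_rough(X)
  model <- fit_forest(X, y[ok], n_trees = n_trees, mtry = mtry,
                      min_node_size = min_node_size, seed = seed)
  imp <- permutation_importance(model)
  groups <- if (!is.null(pd_groups)) {
    factor(covariates[[pd_groups]][match(ids, covariates$stock_id)])
  } else NULL

  two_level <- model$predictors[apply(model$X, 2L, function(c)
    length(unique(c)) == 2L)]
  numeric_preds <- setdiff(model$predictors, two_level)
  pd <- lapply(stats::setNames(numeric_preds, numeric_preds), function(v)
    partial_dependence(model, v, groups = groups))
  mm <- lapply(stats::setNames(two_level, two_level), function(v)
    marginal_means(model, v))

  list(response = response, n = sum(ok), model = model, importance = imp,
       pd = pd, marginal_means = mm)
}

#' End-to-end analysis run
#'
#' Simulates or ingests the fleet, fills missing reference points by Schaefer
#' fits, computes the ten performance measures, applies the scenario, screens
#' collinearity, attributes each response with a bagged forest, runs the
#' foregone-revenue analysis, and (when `out_dir` is set) writes delimited
#' artifacts and figures plus a reproducibility manifest.
#'
#' @param config A [run_config()].
#' @return List with `fleet`, `performance` (full [performance_table()]
#'   output), `scenario_data`, `diagnostics`, `attribution` (one element per
#'   response), `economics`, `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (config$mode == "synthetic") {
    fl <- config$fleet
    fl$seed <- .stage_seed(config$seed, "simulate")
    fleet <- generate_fleet(fl)
  } else {
    rd <- function(f) utils::read.csv(file.path(config$input_dir, f),
                                      stringsAsFactors = FALSE)
    fleet <- list(annual = rd("annual.csv"), covariates = rd("covariates.csv"),
                  stocks = rd("stocks.csv"))
  }

  # reference points for stocks whose targets are not supplied
  need <- which(!is.finite(fleet$stocks$f_target) |
                  !is.finite(fleet$stocks$b_target))
  refits <- list()
  for (i in need) {
    sid <- fleet$stocks$stock_id[i]
    a <- fleet$annual[fleet$annual$stock_id == sid, , drop = FALSE]
    ft <- fit_schaefer(a$catch, a$biomass)
    refits[[sid]] <- ft
    if (!is.finite(fleet$stocks$f_target[i])) {
      fleet$stocks$f_target[i] <- ft$F_MSY
    }
    if (!is.finite(fleet$stocks$b_target[i])) {
      fleet$stocks$b_target[i] <- ft$B_MSY
    }
  }

  perf <- performance_table(fleet$annual, fleet$stocks)
  scen <- apply_scenario(perf$performance, fleet$covariates, fleet$stocks,
                         config$scenario)
  diag_rep <- colinearity_report(
    scen$covariates[, scen$predictors, drop = FALSE])

  attribution <- list()
  for (resp in config$responses) {
    attribution[[resp]] <- attribute_response(
      scen$performance, scen$covariates, resp,
      predictors = scen$predictors,
      n_trees = config$n_trees, mtry = config$mtry,
      min_node_size = config$min_node_size,
      seed = .stage_seed(config$seed, paste0("forest_", resp)),
      pd_groups = if ("region" %in% names(scen$covariates)) "region" else NULL)
  }

  econ <- economics_report(
    fleet$annual[fleet$annual$stock_id %in% scen$performance$stock_id, ,
                 drop = FALSE],
    scen$covariates)

  manifest <- list(
    package_version = as.character(utils::packageVersion("stocktactics")),
    master_seed = config$seed, scenario = config$scenario,
    n_trees = config$n_trees, mtry = config$mtry,
    n_stocks_input = nrow(fleet$stocks),
    n_excluded = nrow(perf$excluded),
    n_after_scenario = nrow(scen$performance),
    n_per_metric = as.list(vapply(config$responses, function(m)
      sum(is.finite(scen$performance[[m]])), integer(1))),
    stage_seeds = as.list(c(
      simulate = .stage_seed(config$seed, "simulate"),
      stats::setNames(
        vapply(config$responses, function(r)
          .stage_seed(config$seed, paste0("forest_", r)), integer(1)),
        paste0("forest_", config$responses)))))

  result <- list(fleet = fleet, performance = perf, scenario_data = scen,
                 diagnostics = diag_rep, attribution = attribution,
                 economics = econ, manifest = manifest)

  if (!is.null(config$out_dir)) .write_run(result, config)
  result
}

# delimited artifacts + manifest + figures under out_dir
.write_run <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(config$out_dir, f),
                                        row.names = FALSE)
  w(result$performance$performance, "performance.csv")
  w(result$performance$excluded, "excluded_stocks.csv")
  w(result$performance$metric_log, "metric_exclusions.csv")
  w(result$diagnostics$gvif, "gvif.csv")
  w(as.data.frame(result$diagnostics$correlations), "correlations.csv")
  w(as.data.frame(result$economics), "value_curve.csv")

  imp <- do.call(rbind, lapply(result$attribution, function(a)
    cbind(response = a$response, a$importance)))
  w(imp, "importance.csv")
  mm <- do.call(rbind, lapply(result$attribution, function(a)
    do.call(rbind, lapply(names(a$marginal_means), function(v) {
      m <- a$marginal_means[[v]]
      data.frame(response = a$response, covariate = v,
                 mean_level0 = m$mean_level0, mean_level1 = m$mean_level1,
                 pct_diff = m$pct_diff)
    }))))
  w(mm, "marginal_means.csv")
  for (a in result$attribution) {
    for (v in names(a$pd)) {
      w(as.data.frame(a$pd[[v]]),
        sprintf("pd_%s_%s.csv", a$response, v))
    }
  }
  yaml::write_yaml(result$manifest, file.path(config$out_dir, "manifest.yaml"))

  cats <- .status_category(
    result$fleet$stocks[match(result$scenario_data$performance$stock_id,
                              result$fleet$stocks$stock_id), , drop = FALSE])
  try(status_panel(result$scenario_data$performance, cats,
                   file = file.path(config$out_dir, "status_plot.png")),
      silent = TRUE)
  invisible(config$out_dir)
}
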