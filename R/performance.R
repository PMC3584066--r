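#' Canonical names of the ten performance measures
#'
#' Mean, standard deviation, and downside semi-deviation of each of the three
#' log status ratios (catch:TAC, F:F_target, B:B_target), plus the pooled
#' discard proportion.
#'
#' @return Character vector of length 10.
#' @export
performance_measures <- function() {
  c("mean_catch_tac", "sd_catch_tac", "semidev_catch_tac",
    "mean_f", "sd_f", "semidev_f",
    "mean_b", "sd_b", "semidev_b",
    "discard_prop")
}

#' Select the snapshot window for a stock
#'
#' Returns the most recent run of `window` consecutive years with data,
#' stepping back past any listed management change: if a change year falls
#' inside the candidate window, the window becomes the most recent eligible
#' run ending before the change year.
#'
#' @param years Integer vector of years with usable data for the metric.
#' @param change_years Years of major management changes (may be empty).
#' @param window Window length in years (default 5).
#' @return Integer vector of `window` consecutive years; when no eligible
#'   window exists (fewer than `window` usable consecutive years) a
#'   zero-length integer vector with the reason in attribute `"reason"`.
#' @export
select_window <- function(years, change_years = integer(0), window = 5L) {
  years <- sort(unique(as.integer(years)))
  change_years <- as.integer(change_years)

  no_window <- structure(
    integer(0),
    reason = sprintf("fewer than %d usable consecutive years", window))

  latest_run_end <- function(max_end) {
    ok <- years[years <= max_end]
    ends <- ok[vapply(ok, function(y) all((y - window + 1L):y %in% ok),
                      logical(1))]
    if (length(ends) == 0L) return(NA_integer_)
    max(ends)
  }

  max_end <- if (length(years)) max(years) else NA_integer_
  repeat {
    if (is.na(max_end)) return(no_window)
    end <- latest_run_end(max_end)
    if (is.na(end)) return(no_window)
    win <- (end - window + 1L):end
    inside <- change_years[change_years %in% win]
    if (length(inside) == 0L) return(win)
    max_end <- min(inside) - 1L  # window must end before the change year
  }
}

#' Apply the stock inclusion rules
#'
#' Excludes stocks whose data end before a cutoff year, stocks with little or
#' no commercial value, stocks under a rebuilding plan during the snapshot
#' window, and stocks co-caught with rebuilding stocks. Each excluded stock is
#' labelled with exactly one primary reason, applied in that order.
#'
#' @param stocks Stock-level table with columns `stock_id`,
#'   `last_data_year`, `low_commercial_value`, `rebuilding_in_window`,
#'   `co_caught_with_rebuilding`.
#' @param min_last_year Stocks with `last_data_year` before this are excluded
#'   (default 2000).
#' @return List with `included` (subset of `stocks`) and `excluded`
#'   (data.frame of `stock_id`, `reason`).
#' @export
filter_stocks <- function(stocks, min_last_year = 2000L) {
  reason <- rep(NA_character_, nrow(stocks))
  pre <- !is.na(stocks$last_data_year) & stocks$last_data_year < min_last_year
  reason[pre] <- sprintf("data only available prior to %d", min_last_year)
  hit <- function(col) is.na(reason) & !is.na(stocks[[col]]) & stocks[[col]]
  reason[hit("low_commercial_value")] <- "little or no commercial value"
  reason[hit("rebuilding_in_window")] <- "under rebuilding plan in window"
  reason[hit("co_caught_with_rebuilding")] <- "co-caught with rebuilding stocks"
  list(
    included = stocks[is.na(reason), , drop = FALSE],
    excluded = data.frame(stock_id = stocks$stock_id[!is.na(reason)],
                          reason = reason[!is.na(reason)],
                          stringsAsFactors = FALSE)
  )
}

#' Match catch components to the scope of the TAC
#'
#' Catch and TAC must describe the same quantity (area, gears, discard and
#' recreational treatment) before a catch:TAC ratio is meaningful. Given a
#' per-year breakdown of catch into named components and a TAC table stating
#' which components each year's TAC covers, this restricts catch to the
#' covered components and drops years with no valid pairing.
#'
#' @param catch_components Data frame with columns `year`, `component`,
#'   `catch`.
#' @param tac_table Data frame with columns `year`, `tac`, `scope`; `scope` is
#'   `"all"` or a comma-separated list of component names covered by the TAC.
#' @return Data frame with columns `year`, `catch`, `tac` (one row per valid
#'   year); dropped years are recorded in attribute `"dropped"` as a data
#'   frame of `year`, `reason`.
#' @export
screen_catch_tac <- function(catch_components, tac_table) {
  stopifnot(all(c("year", "component", "catch") %in% names(catch_components)),
            all(c("year", "tac", "scope") %in% names(tac_table)))
  years <- sort(unique(catch_components$year))
  out <- data.frame(year = integer(0), catch = numeric(0), tac = numeric(0))
  dropped <- data.frame(year = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(y, why) rbind(dropped, data.frame(year = y, reason = why,
                                                     stringsAsFactors = FALSE))
  for (y in years) {
    row <- tac_table[tac_table$year == y, , drop = FALSE]
    if (nrow(row) == 0L || is.na(row$tac[1L])) {
      dropped <- drop(y, "no TAC for year")
      next
    }
    comp <- catch_components[catch_components$year == y, , drop = FALSE]
    scope <- trimws(strsplit(as.character(row$scope[1L]), ",")[[1L]])
    if (!identical(scope, "all")) {
      comp <- comp[comp$component %in% scope, , drop = FALSE]
    }
    if (nrow(comp) == 0L) {
      dropped <- drop(y, "no catch components within TAC scope")
      next
    }
    catch <- sum(comp$catch)
    if (row$tac[1L] == 0 && catch > 0) {
      dropped <- drop(y, "zero TAC with positive catch")
      next
    }
    out <- rbind(out, data.frame(year = y, catch = catch, tac = row$tac[1L]))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Mean and standard deviation of log status ratios
#'
#' Ratios are treated in log space: returns the arithmetic mean and sample
#' standard deviation (n - 1 denominator) of `ln(value/target)` over the
#' window. Non-positive ratios are dropped (and counted in `n_used`).
#'
#' @param values Positive values (e.g. catch, F, or B) in the window.
#' @param target Positive management target; scalar, or one per year (the
#'   per-year TAC for catch:TAC).
#' @return List with `mean`, `sd`, `n_used`.
#' @export
snapshot_metrics <- function(values, target) {
  ratio <- values / target
  ok <- is.finite(ratio) & ratio > 0
  d <- log(ratio[ok])
  list(mean = mean(d), sd = stats::sd(d), n_used = sum(ok))
}

#' Downside semi-deviation of log status ratios
#'
#' Measures variability only on the undesirable side of a management target
#' over the snapshot window: with `d_i = ln(x_i/target)` counted only when on
#' the undesirable side (`d_i > 0` for catch:TAC and F:F_target, `d_i < 0`
#' for B:B_target) and zero otherwise,
#' `delta = sqrt(mean(d_i^2))` (denominator n, the window length). It is zero
#' iff every value in the window is at or more conservative than the target,
#' and strictly increases with any undesirable excursion.
#'
#' @param values Positive values over the window.
#' @param target Positive target (scalar or per-year).
#' @param side `"upper"` when exceeding the target is undesirable (catch:TAC,
#'   F:F_target); `"lower"` when falling below it is (B:B_target).
#' @param method `"rms"` (root-mean-square, default) or `"mean_abs"` (mean of
#'   absolute undesirable deviations).
#' @return Non-negative scalar.
#' @examples
#' semideviation(c(1.1, 0.9, 1.35, 1.0, 0.8), 1, "upper")  # 0.14081...
#' semideviation(c(0.5, 0.9, 1.0, 0.7, 0.2), 1, "upper")   # 0: all at/below
#' @export
semideviation <- function(values, target, side = c("upper", "lower"),
                          method = c("rms", "mean_abs")) {
  side <- match.arg(side)
  method <- match.arg(method)
  if (any(!is.finite(values)) || any(values <= 0) || any(target <= 0)) {
    stop("semideviation() requires positive values and target")
  }
  d <- log(values / target)
  d <- if (side == "upper") pmax(d, 0) else pmin(d, 0)
  if (method == "rms") sqrt(mean(d^2)) else mean(abs(d))
}

#' Pooled discard proportion over the window
#'
#' Total discards divided by total catch across the window years
#' (catch-weighted pooling, robust to near-zero-catch years).
#'
#' @param discards,catch Annual discards and total catch over the window;
#'   discards must not exceed catch in any year.
#' @return Proportion in `[0, 1]`, or `NA` when total catch is zero.
#' @export
discard_proportion <- function(discards, catch) {
  stopifnot(length(discards) == length(catch),
            all(discards <= catch + 1e-12), all(discards >= 0))
  tot <- sum(catch)
  if (tot <= 0) return(NA_real_)
  sum(discards) / tot
}

#' Year of fishery development
#'
#' The first year in which total landings reached 25% of the maximum historic
#' annual landings in the full time series.
#'
#' @param landings Annual landings over the full series.
#' @param years Corresponding years (defaults to `seq_along(landings)`).
#' @return The development year.
#' @export
year_of_development <- function(landings, years = seq_along(landings)) {
  stopifnot(length(landings) == length(years))
  if (all(landings <= 0)) stop("all-zero landings series")
  years[which(landings >= 0.25 * max(landings))[1L]]
}

# metrics for one log-ratio response over its own snapshot window;
# returns NAs (with a reason) when no eligible window exists
.ratio_block <- function(years_avail, change_years, values_by_year,
                         target, side, window = 5L) {
  win <- select_window(years_avail, change_years, window)
  if (length(win) == 0L) {
    return(list(mean = NA_real_, sd = NA_real_, semidev = NA_real_,
                mean_ratio = NA_real_, window = c(NA_integer_, NA_integer_),
                n = 0L, reason = attr(win, "reason")))
  }
  v <- values_by_year[as.character(win)]
  tg <- if (length(target) > 1L) target[as.character(win)] else target
  sm <- snapshot_metrics(v, tg)
  list(mean = sm$mean, sd = sm$sd,
       semidev = semideviation(v, tg, side = side),
       mean_ratio = mean(v / tg),
       window = range(win), n = sm$n_used, reason = NA_character_)
}

#' Compute the ten performance measures for every included stock
#'
#' Applies the inclusion rules, selects a snapshot window per metric (windows
#' may differ across metrics when data coverage differs), and computes the
#' mean, standard deviation and downside semi-deviation of the three log
#' status ratios plus the pooled discard proportion.
#'
#' @param annual Annual records: data frame with columns `stock_id`, `year`,
#'   `biomass`, `F`, `catch`, `tac`, `abc`, `discards`, `landings` (ABC
#'   optional, may be `NA`).
#' @param stocks Stock-level table with `stock_id`, `region`, `taxa`,
#'   `b_target`, `f_target`, the exclusion flags used by [filter_stocks()],
#'   and optionally `management_change_years` (list column).
#' @param window Window length (default 5 years).
#' @return List with `performance` (one row per included stock; `NA` metrics
#'   where no eligible window exists), `excluded` (stock-level exclusions with
#'   reasons), `metric_log` (per stock x metric dropped reasons), and
#'   `n_per_metric` (included sample size for each of the ten measures).
#' @export
performance_table <- function(annual, stocks, window = 5L) {
  flt <- filter_stocks(stocks)
  inc <- flt$included
  logs <- list()

  rows <- lapply(seq_len(nrow(inc)), function(i) {
    sid <- inc$stock_id[i]
    a <- annual[annual$stock_id == sid, , drop = FALSE]
    a <- a[order(a$year), , drop = FALSE]
    chg <- if ("management_change_years" %in% names(inc)) {
      as.integer(unlist(inc$management_change_years[i]))
    } else integer(0)

    # catch:TAC uses the per-year TAC as its target
    ct_ok <- is.finite(a$catch) & is.finite(a$tac) & a$tac > 0 & a$catch > 0
    ct <- .ratio_block(a$year[ct_ok], chg,
                       stats::setNames(a$catch[ct_ok], a$year[ct_ok]),
                       stats::setNames(a$tac[ct_ok], a$year[ct_ok]),
                       side = "upper", window = window)

    f_ok <- is.finite(a$F) & a$F > 0 & is.finite(inc$f_target[i])
    fb <- .ratio_block(a$year[f_ok], chg,
                       stats::setNames(a$F[f_ok], a$year[f_ok]),
                       inc$f_target[i], side = "upper", window = window)

    b_ok <- is.finite(a$biomass) & a$biomass > 0 & is.finite(inc$b_target[i])
    bb <- .ratio_block(a$year[b_ok], chg,
                       stats::setNames(a$biomass[b_ok], a$year[b_ok]),
                       inc$b_target[i], side = "lower", window = window)

    d_ok <- is.finite(a$discards) & is.finite(a$catch)
    dwin <- select_window(a$year[d_ok], chg, window)
    dp <- if (length(dwin) == 0L) NA_real_ else {
      sel <- a$year %in% dwin
      discard_proportion(a$discards[sel], a$catch[sel])
    }

    for (blk in list(c("catch_tac", ct$reason), c("f", fb$reason),
                     c("b", bb$reason))) {
      if (!is.na(blk[2L])) {
        logs[[length(logs) + 1L]] <<- data.frame(
          stock_id = sid, metric = blk[1L], reason = blk[2L],
          stringsAsFactors = FALSE)
      }
    }
    if (length(dwin) == 0L) {
      logs[[length(logs) + 1L]] <<- data.frame(
        stock_id = sid, metric = "discard_prop",
        reason = attr(dwin, "reason"), stringsAsFactors = FALSE)
    }

    data.frame(
      stock_id = sid, region = inc$region[i], taxa = inc$taxa[i],
      mean_catch_tac = ct$mean, sd_catch_tac = ct$sd,
      semidev_catch_tac = ct$semidev, mean_ratio_catch_tac = ct$mean_ratio,
      mean_f = fb$mean, sd_f = fb$sd, semidev_f = fb$semidev,
      mean_b = bb$mean, sd_b = bb$sd, semidev_b = bb$semidev,
      discard_prop = dp,
      window_start_catch_tac = ct$window[1L], window_end_catch_tac = ct$window[2L],
      window_start_f = fb$window[1L], window_end_f = fb$window[2L],
      window_start_b = bb$window[1L], window_end_b = bb$window[2L],
      stringsAsFactors = FALSE)
  })

  perf <- do.call(rbind, rows)
  if (is.null(perf)) perf <- data.frame()
  metric_log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(stock_id = character(0), metric = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  n_per_metric <- vapply(performance_measures(),
                         function(m) sum(is.finite(perf[[m]])), integer(1))
  list(performance = perf, excluded = flt$excluded,
       metric_log = metric_log, n_per_metric = n_per_metric)
}
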