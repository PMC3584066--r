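#' Stock values from ex-vessel price and window means
#'
#' Elementwise products of price with the 5-year mean catch, TAC and (when
#' available) ABC. A missing ABC leaves the ABC value `NA` (omitted, not
#' zeroed).
#'
#' @param price Ex-vessel price (currency per tonne).
#' @param mean_catch,mean_tac,mean_abc Window means (tonnes/yr); `mean_abc`
#'   may be `NA`.
#' @return List with `catch_value`, `tac_value`, `abc_value`.
#' @export
stock_values <- function(price, mean_catch, mean_tac, mean_abc = NA_real_) {
  stopifnot(all(price >= 0, na.rm = TRUE),
            all(mean_catch >= 0, na.rm = TRUE),
            all(mean_tac >= 0, na.rm = TRUE))
  list(catch_value = price * mean_catch,
       tac_value = price * mean_tac,
       abc_value = price * mean_abc)
}

#' Percent loss of potential revenue
#'
#' `100 * (cumulative TAC value / cumulative catch value - 1)`: the revenue
#' foregone by catching less than the TAC, as a percentage of realized catch
#' value.
#'
#' @param cum_tac_value,cum_catch_value Cumulative values (same currency).
#' @return Percent loss (vectorized); `NA` where cumulative catch value is 0.
#' @examples
#' pct_revenue_loss(150, 100)  # 50
#' @export
pct_revenue_loss <- function(cum_tac_value, cum_catch_value) {
  ifelse(cum_catch_value > 0,
         100 * (cum_tac_value / cum_catch_value - 1), NA_real_)
}

#' Cumulative value curve over value-ranked stocks
#'
#' Stocks are ranked by catch value (descending; ties broken by `stock_id`),
#' and cumulative catch, TAC and ABC values are accumulated along the
#' ranking together with the per-rank percent loss of potential revenue.
#'
#' @param values Data frame with `stock_id`, `catch_value`, `tac_value`,
#'   optional `abc_value` and `region`.
#' @param by_region Also compute per-region curves (default `TRUE` when a
#'   `region` column is present).
#' @return Data frame (class `value_curve`) with one row per rank: `rank`,
#'   `stock_id`, `region`, the three cumulative values, and `pct_loss`; for
#'   regional curves, ranks restart within region and rows carry the region
#'   label, with the pooled curve under region `"all"`.
#' @export
value_curve <- function(values, by_region = "region" %in% names(values)) {
  stopifnot(all(c("stock_id", "catch_value", "tac_value") %in% names(values)))
  if (!"abc_value" %in% names(values)) values$abc_value <- NA_real_
  one_curve <- function(v, label) {
    v <- v[order(-v$catch_value, v$stock_id), , drop = FALSE]
    data.frame(
      region = label, rank = seq_len(nrow(v)), stock_id = v$stock_id,
      cum_catch_value = cumsum(v$catch_value),
      cum_tac_value = cumsum(v$tac_value),
      cum_abc_value = cumsum(v$abc_value),
      pct_loss = pct_revenue_loss(cumsum(v$tac_value), cumsum(v$catch_value)),
      stringsAsFactors = FALSE)
  }
  out <- one_curve(values, "all")
  if (by_region) {
    for (rg in sort(unique(values$region))) {
      out <- rbind(out, one_curve(values[values$region == rg, , drop = FALSE],
                                  rg))
    }
  }
  class(out) <- c("value_curve", "data.frame")
  out
}

#' Foregone-revenue analysis over a fleet
#'
#' Computes 5-year window means of catch, TAC and ABC per stock from the
#' annual table, multiplies by ex-vessel price, and builds pooled and
#' per-region cumulative value curves.
#'
#' @param annual Annual records (`stock_id`, `year`, `catch`, `tac`, `abc`).
#' @param covariates Stock table with `stock_id`, `exvessel_price`, and
#'   optionally `region`.
#' @param window Window length (default 5, the most recent years per stock).
#' @return A [value_curve()] data frame.
#' @export
economics_report <- function(annual, covariates, window = 5L) {
  ids <- unique(annual$stock_id)
  rows <- lapply(ids, function(sid) {
    a <- annual[annual$stock_id == sid, , drop = FALSE]
    a <- utils::tail(a[order(a$year), , drop = FALSE], window)
    price <- covariates$exvessel_price[match(sid, covariates$stock_id)]
    v <- stock_values(price, mean(a$catch), mean(a$tac),
                      if (all(is.finite(a$abc))) mean(a$abc) else NA_real_)
    data.frame(stock_id = sid,
               region = if ("region" %in% names(covariates)) {
                 covariates$region[match(sid, covariates$stock_id)]
               } else "all",
               catch_value = v$catch_value, tac_value = v$tac_value,
               abc_value = v$abc_value, stringsAsFactors = FALSE)
  })
  value_curve(do.call(rbind, rows))
}
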