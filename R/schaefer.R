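#' Project biomass forward under Schaefer surplus-production dynamics
#'
#' Deterministic recursion `B[t+1] = B[t] + r*B[t]*(1 - B[t]/K) - C[t]`,
#' floored at a small positive epsilon so that overharvest cannot drive the
#' projected biomass negative.
#'
#' @param r Intrinsic population growth rate (per year), `0 < r`.
#' @param K Carrying capacity (same units as biomass, e.g. tonnes).
#' @param B_start Biomass in the first year.
#' @param catches Numeric vector of annual catches; the projection returns
#'   `length(catches) + 1` biomass values (first year through the year after
#'   the last catch).
#' @param floor_eps Lower bound applied to projected biomass.
#' @return Numeric vector of biomass, length `length(catches) + 1`.
#' @examples
#' schaefer_predict(0.4, 1000, 1000, rep(0, 10))   # stays at K
#' schaefer_predict(0.4, 1000, 500, rep(100, 10))  # MSY equilibrium
#' @export
schaefer_predict <- function(r, K, B_start, catches, floor_eps = 1e-6) {
  stopifnot(is.numeric(r), is.numeric(K), is.numeric(B_start),
            r > 0, K > 0, B_start > 0, all(catches >= 0))
  n <- length(catches)
  B <- numeric(n + 1L)
  B[1L] <- B_start
  for (t in seq_len(n)) {
    B[t + 1L] <- max(B[t] + r * B[t] * (1 - B[t] / K) - catches[t], floor_eps)
  }
  B
}

#' MSY-based reference points under the Schaefer model
#'
#' Closed forms implied by the logistic surplus-production curve:
#' `MSY = r*K/4`, `B_MSY = K/2`, `F_MSY = r/2`, where F is the annual
#' exploitation fraction (catch / biomass).
#'
#' @param r Intrinsic growth rate (per year).
#' @param K Carrying capacity.
#' @return Named list with `MSY`, `B_MSY`, `F_MSY`.
#' @examples
#' msy_refs(0.4, 1000)  # MSY 100, B_MSY 500, F_MSY 0.2
#' @export
msy_refs <- function(r, K) {
  if (!is.numeric(r) || !is.numeric(K) || length(r) != 1L || length(K) != 1L ||
      is.na(r) || is.na(K) || r <= 0 || K <= 0) {
    stop("msy_refs() requires scalar r > 0 and K > 0")
  }
  list(MSY = r * K / 4, B_MSY = K / 2, F_MSY = r / 2)
}

# observation-error SSE on log biomass for a (log r, log K, log B_start)
# parameter vector; used by the multistart optimizer
.schaefer_sse <- function(par, catches, log_b_obs) {
  r <- exp(par[1L]); K <- exp(par[2L]); B0 <- exp(par[3L])
  pred <- schaefer_predict(r, K, B0, catches)[seq_along(log_b_obs)]
  sum((log_b_obs - log(pred))^2)
}

#' Fit a Schaefer surplus-production model to catch and biomass series
#'
#' Estimates `r`, `K` and the first-year biomass by minimizing the sum of
#' squared log residuals between observed and projected biomass
#' (observation-error estimator). A coarse multistart grid over `(r, K)` is
#' refined with bounded quasi-Newton optimization; MSY-based reference points
#' are filled in from the closed forms. Intended for stocks whose assessments
#' publish biomass and catch series but no reference points.
#'
#' @param catches Annual catch series.
#' @param biomass_obs Annual observed total biomass, same length, all positive.
#' @param r_grid,k_mult Multistart grid: candidate `r` values and multipliers
#'   of `max(biomass_obs)` giving candidate `K` values.
#' @return Object of class `schaefer_fit`: list with `r`, `K`, `B_start`,
#'   `MSY`, `B_MSY`, `F_MSY`, `sse`, `converged`, `n_years_used`.
#'   `converged` is `FALSE` (never an error) when the optimizer stops on a
#'   bound or the solution is not identifiable (e.g. no production signal:
#'   near-constant biomass with negligible catch).
#' @export
fit_schaefer <- function(catches, biomass_obs,
                         r_grid = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.5),
                         k_mult = c(1, 1.5, 2, 3, 5)) {
  if (length(catches) != length(biomass_obs)) {
    stop("catches and biomass_obs must have equal length")
  }
  if (length(catches) < 8L) stop("need at least 8 paired years")
  if (any(!is.finite(biomass_obs)) || any(biomass_obs <= 0)) {
    stop("biomass_obs must be positive and finite")
  }
  if (any(!is.finite(catches)) || any(catches < 0)) {
    stop("catches must be non-negative and finite")
  }

  log_b <- log(biomass_obs)
  b_max <- max(biomass_obs)
  lower <- c(log(1e-4), log(b_max * 0.5), log(b_max * 1e-3))
  upper <- c(log(2), log(b_max * 20), log(b_max * 40))

  starts <- expand.grid(r = r_grid, K = k_mult * b_max)
  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    par0 <- c(log(starts$r[i]), log(starts$K[i]), log(biomass_obs[1L]))
    fits[[i]] <- tryCatch(
      stats::optim(par0, .schaefer_sse, catches = catches, log_b_obs = log_b,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e1, maxit = 500L)),
      error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("all multistart fits failed")

  sses <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(sses)]]
  # polish with tighter finite-difference steps than the default 1e-3
  polish <- tryCatch(
    stats::optim(best$par, .schaefer_sse, catches = catches, log_b_obs = log_b,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1, maxit = 500L,
                                ndeps = rep(1e-7, 3L))),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  r <- exp(best$par[1L]); K <- exp(best$par[2L]); B0 <- exp(best$par[3L])

  # boundary check (within a relative hair of the box)
  at_bound <- any(abs(best$par - lower) < 1e-6) || any(abs(best$par - upper) < 1e-6)

  # identifiability: if several starts reach essentially the best SSE with
  # widely different r, the production signal does not pin the parameters down
  tol <- max(min(sses) * 1e-4, 1e-8)
  near <- which(sses <= min(sses) + tol)
  r_near <- exp(vapply(fits[near], function(f) f$par[1L], numeric(1)))
  unidentifiable <- length(near) > 1L && max(r_near) / min(r_near) > 1.5

  refs <- msy_refs(r, K)
  structure(list(
    r = r, K = K, B_start = B0,
    MSY = refs$MSY, B_MSY = refs$B_MSY, F_MSY = refs$F_MSY,
    sse = best$value,
    converged = best$convergence == 0L && !at_bound && !unidentifiable,
    n_years_used = length(catches)
  ), class = "schaefer_fit")
}

#' @export
print.schaefer_fit <- function(x, ...) {
  cat("Schaefer surplus-production fit (observation error on log biomass)\n")
  cat(sprintf("  r = %.4f  K = %.1f  B_start = %.1f  (n = %d years)\n",
              x$r, x$K, x$B_start, x$n_years_used))
  cat(sprintf("  MSY = %.2f  B_MSY = %.1f  F_MSY = %.4f\n",
              x$MSY, x$B_MSY, x$F_MSY))
  cat(sprintf("  SSE(log B) = %.6g   converged: %s\n", x$sse, x$converged))
  invisible(x)
}
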