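#' Two-dimensional Gaussian kernel density on a regular grid
#'
#' Isotropic Gaussian product kernel: the bandwidth is the kernel standard
#' deviation applied on both axes. The grid spans the data range padded by
#' three bandwidths (so the density integrates to ~1 over the grid).
#'
#' @param x,y Point coordinates (at least 2 points).
#' @param bandwidth Kernel SD on both axes (default 2, on the ratio scale of
#'   the status plot).
#' @param n Grid resolution per axis (default 101).
#' @param pad Padding in bandwidths beyond the data range (default 3).
#' @return List of class `density_grid`: `x`, `y` (grid coordinates), `z`
#'   (density matrix, `n x n`), `bandwidth`.
#' @export
kde2d_grid <- function(x, y, bandwidth = 2, n = 101L, pad = 3) {
  stopifnot(length(x) == length(y), length(x) >= 2L, bandwidth > 0)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    warning("all points identical; density is a single peak")
  }
  gx <- seq(min(x) - pad * bandwidth, max(x) + pad * bandwidth, length.out = n)
  gy <- seq(min(y) - pad * bandwidth, max(y) + pad * bandwidth, length.out = n)
  # average of product kernels: z[i, j] = mean_k phi(gx[i]-x[k]) phi(gy[j]-y[k])
  ax <- stats::dnorm(outer(gx, x, "-") / bandwidth) / bandwidth
  ay <- stats::dnorm(outer(gy, y, "-") / bandwidth) / bandwidth
  z <- tcrossprod(ax, ay) / length(x)  # n x n, rows follow gx
  structure(list(x = gx, y = gy, z = z, bandwidth = bandwidth),
            class = "density_grid")
}

# category used by the status panels; mirrors the stock-level exclusion flags
.status_category <- function(stocks) {
  ifelse(stocks$rebuilding_in_window, "rebuilding",
         ifelse(stocks$co_caught_with_rebuilding, "co-caught with rebuilding",
                ifelse(stocks$low_commercial_value, "little commercial value",
                       "targeted")))
}

#' Stock-status panel plot with kernel density contours
#'
#' Scatter of 5-year mean B:B_target (x) against F:F_target (y), panelled by
#' category, with dashed target cross-hairs at ratio 1, symbols by taxa,
#' colours by region, and Gaussian kernel density contours (bandwidth 2 on
#' the ratio scale) overlaid per panel.
#'
#' @param performance Performance table (from [performance_table()]`$performance`)
#'   with `mean_b`, `mean_f` (log-ratio means), `region`, `taxa`.
#' @param categories Character vector (length `nrow(performance)`) giving the
#'   panel of each stock; a single category plots one panel. Categories
#'   partition the stocks.
#' @param bandwidth Kernel SD for the density contours (default 2).
#' @param file Optional PNG path; when given, the figure is written there and
#'   a companion CSV of the plotted coordinates is written alongside it.
#' @return Invisibly, the plotted data (`stock_id`, `category`, `b_ratio`,
#'   `f_ratio`, `region`, `taxa`).
#' @export
status_panel <- function(performance, categories = NULL, bandwidth = 2,
                         file = NULL) {
  dat <- data.frame(
    stock_id = performance$stock_id,
    category = if (is.null(categories)) "targeted" else categories,
    b_ratio = exp(performance$mean_b),
    f_ratio = exp(performance$mean_f),
    region = performance$region, taxa = performance$taxa,
    stringsAsFactors = FALSE)
  dat <- dat[is.finite(dat$b_ratio) & is.finite(dat$f_ratio), , drop = FALSE]

  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 500 *
                     max(1, ceiling(length(unique(dat$category)) / 2)),
                   res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    utils::write.csv(dat, sub("\\.png$", "_data.csv", file),
                     row.names = FALSE)
  }

  cats <- sort(unique(dat$category))
  old <- graphics::par(mfrow = c(max(1, ceiling(length(cats) / 2)),
                                 min(2, length(cats))))
  on.exit(graphics::par(old), add = TRUE)
  regions <- sort(unique(dat$region))
  cols <- stats::setNames(grDevices::hcl.colors(max(3, length(regions)),
                                                "Dark 3")[seq_along(regions)],
                          regions)
  for (ct in cats) {
    d <- dat[dat$category == ct, , drop = FALSE]
    xlim <- range(c(0, 2, d$b_ratio)); ylim <- range(c(0, 2, d$f_ratio))
    graphics::plot(d$b_ratio, d$f_ratio, xlim = xlim, ylim = ylim,
                   xlab = "B : B_target", ylab = "F : F_target",
                   main = ct, col = cols[d$region],
                   pch = ifelse(d$taxa, 17, 19))
    graphics::abline(h = 1, v = 1, lty = 2)
    if (nrow(d) >= 2L && (stats::sd(d$b_ratio) > 0 || stats::sd(d$f_ratio) > 0)) {
      kd <- kde2d_grid(d$b_ratio, d$f_ratio, bandwidth = bandwidth)
      graphics::contour(kd$x, kd$y, kd$z, add = TRUE, drawlabels = FALSE,
                        col = "grey40")
    }
    graphics::legend("topright", legend = regions, col = cols[regions],
                     pch = 19, bty = "n", cex = 0.8)
  }
  invisible(dat)
}

#' Plot a partial-dependence panel
#'
#' Draws the overall marginal curve (line thickness proportional to the
#' covariate's relative importance), per-group curves, decile tick marks, and
#' grey shading over the lower and upper 10% of covariate values.
#'
#' @param pd A [partial_dependence()] curve.
#' @param importance Relative importance score in `[0, 1]` controlling line
#'   width.
#' @param ylab Response label.
#' @return Invisibly, `pd`.
#' @export
plot_partial_dependence <- function(pd, importance = 1,
                                    ylab = "partial dependence") {
  band <- attr(pd, "band80")
  rng <- range(pd$grid)
  ylim <- range(unlist(pd[, -1L]), na.rm = TRUE)
  graphics::plot(NA, xlim = rng, ylim = ylim,
                 xlab = attr(pd, "covariate"), ylab = ylab)
  usr <- graphics::par("usr")
  graphics::rect(usr[1L], usr[3L], band[1L], usr[4L],
                 col = grDevices::grey(0.9), border = NA)
  graphics::rect(band[2L], usr[3L], usr[2L], usr[4L],
                 col = grDevices::grey(0.9), border = NA)
  gcols <- names(pd)[startsWith(names(pd), "yhat_")]
  for (g in gcols) graphics::lines(pd$grid, pd[[g]], col = "grey55")
  graphics::lines(pd$grid, pd$yhat, lwd = 0.5 + 4 * importance)
  graphics::axis(1, at = attr(pd, "deciles"), labels = FALSE, tcl = 0.4)
  graphics::abline(h = 0, lty = 3)
  graphics::box()
  invisible(pd)
}
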