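#' Pairwise Pearson correlations among numeric covariates
#'
#' Computed on pairwise-complete observations. Entries involving a constant
#' column are `NA` and flagged.
#'
#' @param X Data frame or matrix of numeric covariates.
#' @param flag_threshold Absolute correlation flagged as a collinearity
#'   concern (default 0.5).
#' @return Correlation matrix with attribute `"flagged"` (data frame of
#'   pairs with `|r| >=` threshold).
#' @export
pairwise_correlations <- function(X, flag_threshold = 0.5) {
  Xm <- as.matrix(as.data.frame(X))
  storage.mode(Xm) <- "double"
  suppressWarnings(R <- stats::cor(Xm, use = "pairwise.complete.obs"))
  diag(R) <- 1
  idx <- which(upper.tri(R) & abs(R) >= flag_threshold & is.finite(R),
               arr.ind = TRUE)
  attr(R, "flagged") <- data.frame(
    var1 = colnames(R)[idx[, 1L]], var2 = colnames(R)[idx[, 2L]],
    r = R[idx], stringsAsFactors = FALSE)
  R
}

# expand a predictor data frame into design columns; logicals -> 0/1,
# factors/characters with k levels -> k-1 indicators (one multi-column group)
.encode_predictors <- function(X) {
  X <- as.data.frame(X)
  cols <- list(); groups <- character(0)
  for (nm in names(X)) {
    v <- X[[nm]]
    if (is.logical(v)) {
      cols[[nm]] <- as.numeric(v); groups <- c(groups, nm)
    } else if (is.factor(v) || is.character(v)) {
      f <- factor(v)
      for (lev in levels(f)[-1L]) {
        cn <- paste0(nm, lev)
        cols[[cn]] <- as.numeric(f == lev)
        groups <- c(groups, nm)
      }
    } else {
      cols[[nm]] <- as.numeric(v); groups <- c(groups, nm)
    }
  }
  list(design = do.call(cbind, cols), groups = groups)
}

#' Generalized variance inflation factors
#'
#' For each predictor (a single column, or the indicator-column group of a
#' categorical predictor), `GVIF = det(R_j) * det(R_-j) / det(R)` where `R`
#' is the correlation matrix of the full encoded design, `R_j` the submatrix
#' for the predictor's columns and `R_-j` for all other columns. For a
#' single-column predictor this is the classical `VIF = 1/(1 - R^2)` from
#' regressing that column on the others.
#'
#' @param X Data frame of predictors (numeric, logical, factor/character).
#' @param flag_threshold GVIF value flagged as a collinearity concern
#'   (default 2.5).
#' @return Data frame with `predictor`, `df` (columns in the group), `gvif`,
#'   `flagged`. Rank-deficient predictors get `Inf`.
#' @export
gvif <- function(X, flag_threshold = 2.5) {
  enc <- .encode_predictors(X)
  D <- enc$design
  keep <- apply(D, 2L, function(c) stats::sd(c) > 0)
  if (!all(keep)) {
    warning("constant design columns dropped: ",
            paste(colnames(D)[!keep], collapse = ", "))
    D <- D[, keep, drop = FALSE]
    enc$groups <- enc$groups[keep]
  }
  R <- stats::cor(D)
  detR <- det(R)
  preds <- unique(enc$groups)
  out <- data.frame(predictor = preds, df = NA_integer_, gvif = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(preds)) {
    j <- which(enc$groups == preds[i])
    out$df[i] <- length(j)
    if (detR <= .Machine$double.eps) {
      out$gvif[i] <- Inf
      next
    }
    det_j <- det(R[j, j, drop = FALSE])
    det_rest <- det(R[-j, -j, drop = FALSE])
    out$gvif[i] <- det_j * det_rest / detR
  }
  out$flagged <- is.infinite(out$gvif) | out$gvif >= flag_threshold
  out
}

#' Collinearity screening report
#'
#' Combines [pairwise_correlations()] over the numeric covariates with
#' [gvif()] over all predictors, flagging `|r| >= 0.5` and `GVIF >= 2.5`.
#'
#' @param X Data frame of all predictors.
#' @return List of class `colinearity_report` with `correlations`, `gvif`,
#'   and `clean` (`TRUE` when nothing is flagged).
#' @export
colinearity_report <- function(X) {
  num <- vapply(as.data.frame(X), is.numeric, logical(1))
  cors <- pairwise_correlations(as.data.frame(X)[, num, drop = FALSE])
  g <- gvif(X)
  structure(list(correlations = cors, gvif = g,
                 clean = nrow(attr(cors, "flagged")) == 0L && !any(g$flagged)),
            class = "colinearity_report")
}

#' @export
print.colinearity_report <- function(x, ...) {
  cat("Collinearity screening\n")
  fl <- attr(x$correlations, "flagged")
  cat(sprintf("  pairwise |r| >= 0.5: %d pair(s)\n", nrow(fl)))
  cat(sprintf("  GVIF >= 2.5: %d predictor(s)\n", sum(x$gvif$flagged)))
  cat(sprintf("  clean: %s\n", x$clean))
  invisible(x)
}
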