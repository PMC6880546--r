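#' In-sample coefficient refit versus the fixed-coefficient score
#'
#' Re-estimates the CpG coefficients of a score in the evaluation sample
#' itself: fits the outcome on (i) age/sex/BMI covariates only and (ii)
#' covariates plus the individual CpG columns of one coefficient set. The
#' refit's in-sample (unadjusted) R-squared always dominates that of any
#' fixed-weight score built from the same CpGs (the fixed score lies in the
#' refit design's column span), which is exactly the overfitting mechanism
#' that inflates in-sample evaluations of externally trained predictors;
#' adjusted R-squared and out-of-fold R-squared (see [crossval_r2()]) expose
#' the gap.
#'
#' @param meth_resid Residualized methylation matrix restricted (or
#'   restrictable) to the CpGs of interest; columns not in `cpgs` are
#'   ignored.
#' @param covars Data frame with `sample_id`, `age`, `sex`, `bmi`.
#' @param outcome Named numeric outcome vector (names = sample ids).
#' @param cpgs Character vector of CpG column names to refit (default: all
#'   columns of `meth_resid`).
#' @return List of class `refit_comparison`: `covariates_only` and
#'   `refit` (`ols_fit`s on identical samples), plus `incremental_adj_r2`.
#' @export
refit_comparison <- function(meth_resid, covars, outcome,
                             cpgs = colnames(meth_resid)) {
  stopifnot(is.matrix(meth_resid), "sample_id" %in% names(covars))
  cpgs <- intersect(cpgs, colnames(meth_resid))
  if (!length(cpgs)) stop("none of the requested CpGs are in the matrix")
  ids <- Reduce(intersect, list(rownames(meth_resid), covars$sample_id,
                                names(outcome)))
  if (!length(ids)) stop("no overlapping samples between inputs")
  cv <- covars[match(ids, covars$sample_id), c("age", "sex", "bmi")]
  M <- meth_resid[ids, cpgs, drop = FALSE]
  y <- as.numeric(outcome[ids])
  p_total <- ncol(cv) + ncol(M)
  if (length(ids) <= p_total + 1L) {
    stop("parameter count (", p_total, ") too close to sample size (",
         length(ids), "); refusing to refit")
  }
  base_fit <- fit_ols(y, as.matrix(cv))
  full_fit <- fit_ols(y, cbind(as.matrix(cv), M))
  structure(list(covariates_only = base_fit, refit = full_fit,
                 incremental_adj_r2 = full_fit$adj_r2 - base_fit$adj_r2,
                 n = length(ids), n_cpgs = ncol(M)),
            class = "refit_comparison")
}

#' @export
print.refit_comparison <- function(x, ...) {
  cat("<refit_comparison> n = ", x$n, ", ", x$n_cpgs, " CpGs refit\n",
      "  covariates only: adj R2 = ", sprintf("%.4f", x$covariates_only$adj_r2),
      "\n  covariates + CpGs: R2 = ", sprintf("%.4f", x$refit$r2),
      ", adj R2 = ", sprintf("%.4f", x$refit$adj_r2),
      "\n  incremental adj R2 = ", sprintf("%.4f", x$incremental_adj_r2),
      "\n", sep = "")
  invisible(x)
}

#' Out-of-fold R-squared by k-fold cross-validation
#'
#' Fits OLS (intercept included) on k-1 folds and predicts the held-out
#' fold; returns \eqn{1 - \mathrm{PRESS}/\mathrm{TSS}} over the assembled
#' out-of-fold predictions. Fold assignment uses the current RNG state, so
#' seed before calling for reproducibility.
#'
#' @param y Outcome vector.
#' @param X Predictor matrix (no intercept column).
#' @param k Number of folds (default 5).
#' @return Out-of-fold R-squared (can be negative for overfit models).
#' @export
crossval_r2 <- function(y, X, k = 5) {
  y <- as.numeric(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, k >= 2, n >= 2 * k)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    D <- cbind(1, X[tr, , drop = FALSE])
    qd <- qr(D)
    if (qd$rank < ncol(D)) {
      stop("rank-deficient training design in fold ", f)
    }
    b <- qr.coef(qd, y[tr])
    pred[!tr] <- drop(cbind(1, X[!tr, , drop = FALSE]) %*% b)
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}
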