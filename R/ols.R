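#' Ordinary least squares fit with the standard report quantities
#'
#' Closed-form OLS via QR with an intercept always included. Reports
#' coefficients, standard errors, two-sided t-distribution p-values,
#' R-squared and adjusted R-squared
#' \deqn{R^2_{adj} = 1 - (1 - R^2)\frac{n-1}{n-p-1}}
#' with \eqn{p} the number of non-intercept terms. Adjusted R-squared may be
#' negative and is reported as-is.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric matrix or data frame of predictors (no intercept
#'   column; one is added). A plain vector is treated as one predictor.
#' @return Object of class `ols_fit`: list with `terms`, `beta`, `se`,
#'   `t`, `p`, `r2`, `adj_r2`, `n`, `df_model`, `sigma`, `residuals`,
#'   `fitted`.
#' @export
fit_ols <- function(y, X) {
  y <- as.numeric(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                   dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("y and X have different lengths")
  if (any(!is.finite(y)) || any(!is.finite(X))) {
    stop("non-finite values in regression inputs")
  }
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) {
    stop("too few observations (n = ", n, ") for ", p,
         " predictors plus intercept")
  }
  D <- cbind(`(Intercept)` = 1, X)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    aliased <- colnames(D)[qd$pivot[(qd$rank + 1L):ncol(D)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qd, y)
  fitted <- drop(D %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("outcome has zero variance")
  df_res <- n - p - 1L
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(qr.R(qd))[order(qd$pivot), order(qd$pivot), drop = FALSE]
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = df_res, lower.tail = FALSE)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(terms = colnames(D), beta = unname(beta), se = unname(se),
                 t = unname(tval), p = unname(pval),
                 r2 = r2, adj_r2 = adj_r2, n = n, df_model = p,
                 sigma = sqrt(sigma2), residuals = res, fitted = fitted),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("<ols_fit> n = ", x$n, ", R2 = ", sprintf("%.4f", x$r2),
      ", adj R2 = ", sprintf("%.4f", x$adj_r2), "\n", sep = "")
  tab <- data.frame(term = x$terms, beta = x$beta, se = x$se, p = x$p)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Coefficient table of an OLS fit
#' @param fit An `ols_fit`.
#' @return Data frame with term, beta, se, t, p.
#' @export
ols_coefficients <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  data.frame(term = fit$terms, beta = fit$beta, se = fit$se,
             t = fit$t, p = fit$p)
}

#' Variance in an outcome explained by a score
#'
#' Single-predictor OLS of the outcome on the score; `r2` / `adj_r2` of the
#' returned fit are the fractions reported (multiplied by 100 only at
#' presentation time).
#'
#' @param score Numeric score vector (e.g. from [compute_score()]).
#' @param outcome Numeric outcome vector aligned with `score`. If both are
#'   named, they are aligned on their common names.
#' @return An `ols_fit` with a single `score` term.
#' @export
variance_explained <- function(score, outcome) {
  s <- as.numeric(score)
  o <- as.numeric(outcome)
  if (!is.null(names(score)) && !is.null(names(outcome))) {
    ids <- intersect(names(score), names(outcome))
    if (!length(ids)) stop("no overlapping sample names between score and outcome")
    s <- as.numeric(score[ids])
    o <- as.numeric(outcome[ids])
  } else if (length(s) != length(o)) {
    stop("score and outcome have different lengths and no names to align on")
  }
  fit_ols(o, matrix(s, ncol = 1, dimnames = list(NULL, "score")))
}
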