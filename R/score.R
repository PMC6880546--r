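#' Compute a weighted CpG methylation score
#'
#' The biomarker score for sample \eqn{s} is the weighted sum
#' \deqn{S_s = \sum_i \beta_i \, m_{s,i}}
#' over the CpGs of one coefficient set, where \eqn{m_{s,i}} is the (usually
#' covariate-residualized) methylation value of sample \eqn{s} at CpG
#' \eqn{i}. There is no intercept: the absolute location of the score is
#' arbitrary, and every downstream analysis (R-squared, AUC, OLS slopes on
#' standardized scores) is invariant to it.
#'
#' Array-platform attrition (e.g. 450K probes absent from EPIC) is the
#' realistic failure mode for fixed published coefficient sets, so missing
#' CpGs are governed by `missing_policy`:
#' \describe{
#'   \item{`"error"`}{any missing coefficient CpG is an error (default);}
#'   \item{`"drop"`}{missing CpGs are omitted from the sum with a warning,
#'     provided coverage stays at or above `coverage_floor`;}
#'   \item{`"impute_zero"`}{missing CpGs contribute 0. Only meaningful on
#'     residualized input, where 0 is the covariate-predicted mean.}
#' }
#'
#' @param meth Numeric matrix, samples in rows (rownames = sample ids),
#'   CpGs in columns (colnames = CpG ids).
#' @param coefs A `coef_set` (see [coefficient_set()]).
#' @param missing_policy One of `"error"`, `"drop"`, `"impute_zero"`.
#' @param coverage_floor Minimum fraction of coefficient CpGs that must be
#'   present in `meth` (default 0.95).
#' @return A named numeric vector of scores (one per sample) of class
#'   `dnam_score`, with attributes `set_name` and `coverage`.
#' @export
compute_score <- function(meth, coefs,
                          missing_policy = c("error", "drop", "impute_zero"),
                          coverage_floor = 0.95) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(coefs, "coef_set"), is.matrix(meth))
  if (is.null(colnames(meth)) || is.null(rownames(meth))) {
    stop("methylation matrix must have sample rownames and CpG colnames")
  }
  w <- coefs$weights
  present <- names(w) %in% colnames(meth)
  coverage <- mean(present)
  if (coverage == 0) {
    stop("none of the ", coefs$n_cpgs, " CpGs of set '", coefs$name,
         "' are present in the methylation matrix")
  }
  if (coverage < 1) {
    miss <- sum(!present)
    if (missing_policy == "error") {
      stop(miss, " of ", coefs$n_cpgs, " CpGs of set '", coefs$name,
           "' missing from the matrix (coverage ",
           sprintf("%.3f", coverage), "); set missing_policy to proceed")
    }
    if (missing_policy == "drop" && coverage < coverage_floor) {
      stop("coverage ", sprintf("%.3f", coverage),
           " below floor ", coverage_floor, " for set '", coefs$name,
           "' under missing_policy = 'drop'")
    }
    if (missing_policy == "drop") {
      warning(miss, " CpG(s) of set '", coefs$name,
              "' dropped from score (coverage ",
              sprintf("%.3f", coverage), ")")
    } else if (coverage < coverage_floor) {
      warning("coverage ", sprintf("%.3f", coverage), " below floor ",
              coverage_floor, " for set '", coefs$name,
              "'; missing CpGs imputed as 0")
    }
    w <- w[present]
  }
  score <- as.vector(meth[, names(w), drop = FALSE] %*% w)
  structure(stats::setNames(score, rownames(meth)),
            set_name = coefs$name, coverage = coverage,
            class = "dnam_score")
}

#' @export
print.dnam_score <- function(x, ...) {
  cat("<dnam_score> set ", attr(x, "set_name"), ", n = ", length(x),
      ", coverage = ", sprintf("%.3f", attr(x, "coverage")), "\n", sep = "")
  print(utils::head(unclass(x)))
  invisible(x)
}
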