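#' Earlier-versus-concurrent biomarker regression design
#'
#' The confounding test at the heart of the longitudinal analysis: if a
#' methylation score were driven by stable genotype or stable early
#' environment, a score computed from blood drawn years earlier should
#' predict a later outcome about as well as the concurrent score. Three OLS
#' fits are returned: outcome on the earlier score alone, on the concurrent
#' score alone, and on both jointly. A null earlier effect alongside a
#' strong concurrent effect argues against stable confounding.
#'
#' Samples are paired complete-case on the names of the three vectors; the
#' paired N is reported. By default scores are standardized to unit
#' variance within the paired subsample so coefficients are per SD of
#' score; set `standardize = FALSE` for raw-scale coefficients.
#'
#' @param outcome Named numeric outcome (e.g. AUDIT) at the later time.
#' @param score_early Named score vector from the earlier collection.
#' @param score_concurrent Named score vector concurrent with the outcome.
#' @param labels Length-2 character: term labels for the early and
#'   concurrent scores (used in report tables).
#' @param standardize Standardize scores within the paired subsample?
#' @return Object of class `longitudinal_fit`: list with `n`, `models`
#'   (named list of `ols_fit`: `early`, `concurrent`, `joint`) and
#'   `labels`.
#' @export
early_vs_concurrent <- function(outcome, score_early, score_concurrent,
                                labels = c("early", "concurrent"),
                                standardize = TRUE) {
  ids <- Reduce(intersect, lapply(list(outcome, score_early, score_concurrent),
                                  names))
  if (length(ids) <= 10) {
    stop("paired sample too small (n = ", length(ids), "); need n > 10")
  }
  y <- as.numeric(outcome[ids])
  e <- as.numeric(score_early[ids])
  c_ <- as.numeric(score_concurrent[ids])
  if (stats::sd(e) == 0 || stats::sd(c_) == 0) {
    stop("a score vector has zero variance in the paired subsample")
  }
  if (abs(stats::cor(e, c_)) > 1 - 1e-10) {
    stop("early and concurrent scores are collinear (|r| ~ 1); ",
         "were they computed from the same arrays?")
  }
  if (standardize) {
    e <- as.numeric(scale(e)); c_ <- as.numeric(scale(c_))
  }
  X2 <- cbind(e, c_)
  colnames(X2) <- labels
  models <- list(
    early      = fit_ols(y, matrix(e, ncol = 1, dimnames = list(NULL, labels[1]))),
    concurrent = fit_ols(y, matrix(c_, ncol = 1, dimnames = list(NULL, labels[2]))),
    joint      = fit_ols(y, X2)
  )
  structure(list(n = length(ids), models = models, labels = labels,
                 standardized = standardize),
            class = "longitudinal_fit")
}

#' Birth / maternal-pregnancy extension of the longitudinal design
#'
#' Tests whether a suggestive association between a score at birth and the
#' offspring's adolescent outcome could be driven by maternal drinking in
#' pregnancy: fits the outcome on the offspring birth score and the
#' maternal pregnancy score singly and jointly (optionally also adding the
#' offspring's concurrent adolescent score). Vectors are aligned on their
#' names, which must be a shared family/pair key.
#'
#' @param outcome Named adolescent outcome vector (family-keyed).
#' @param score_birth Named offspring cord-blood score.
#' @param score_maternal Named maternal pregnancy score.
#' @param score_concurrent Optional named offspring adolescent score.
#' @param standardize Standardize scores within the paired subsample?
#' @return `longitudinal_fit`-like object of class `maternal_fit` with
#'   models `birth`, `maternal`, `joint` (birth + maternal) and, when the
#'   concurrent score is given, `joint_concurrent`.
#' @export
birth_maternal_extension <- function(outcome, score_birth, score_maternal,
                                     score_concurrent = NULL,
                                     standardize = TRUE) {
  vecs <- list(outcome, score_birth, score_maternal)
  if (!is.null(score_concurrent)) vecs <- c(vecs, list(score_concurrent))
  ids <- Reduce(intersect, lapply(vecs, names))
  n_in <- length(names(outcome))
  if (length(ids) < n_in) {
    message(n_in - length(ids), " unpaired sample(s) dropped from the ",
            "maternal extension")
  }
  if (length(ids) < 10) {
    stop("paired sample too small (n = ", length(ids), "); need n >= 10")
  }
  y <- as.numeric(outcome[ids])
  b <- as.numeric(score_birth[ids])
  m <- as.numeric(score_maternal[ids])
  if (stats::sd(b) == 0 || stats::sd(m) == 0) {
    stop("degenerate (zero-variance) score in the paired subsample")
  }
  if (standardize) {
    b <- as.numeric(scale(b)); m <- as.numeric(scale(m))
  }
  models <- list(
    birth    = fit_ols(y, matrix(b, ncol = 1, dimnames = list(NULL, "birth"))),
    maternal = fit_ols(y, matrix(m, ncol = 1, dimnames = list(NULL, "maternal_pregnancy"))),
    joint    = fit_ols(y, cbind(birth = b, maternal_pregnancy = m))
  )
  if (!is.null(score_concurrent)) {
    a <- as.numeric(score_concurrent[ids])
    if (standardize) a <- as.numeric(scale(a))
    models$joint_concurrent <-
      fit_ols(y, cbind(birth = b, maternal_pregnancy = m, adolescence = a))
  }
  structure(list(n = length(ids), models = models,
                 standardized = standardize),
            class = "maternal_fit")
}

#' Longitudinal report table
#'
#' Flattens a [early_vs_concurrent()] or [birth_maternal_extension()] result
#' into the report layout: one row per model, joint-model coefficients
#' comma-combined, columns `dependent`, `independent`, `n`, `beta`, `se`,
#' `p`, `adj_r2`.
#'
#' @param fit A `longitudinal_fit` or `maternal_fit`.
#' @param dependent Label for the outcome column.
#' @return Data frame in the fixed column order.
#' @export
longitudinal_table <- function(fit, dependent = "AUDIT") {
  stopifnot(inherits(fit, c("longitudinal_fit", "maternal_fit")))
  fmt <- function(x) paste(sprintf("%.3g", x), collapse = ", ")
  rows <- lapply(names(fit$models), function(nm) {
    m <- fit$models[[nm]]
    keep <- m$terms != "(Intercept)"
    data.frame(dependent = dependent,
               independent = paste(m$terms[keep], collapse = " + "),
               n = m$n,
               beta = fmt(m$beta[keep]),
               se = fmt(m$se[keep]),
               p = fmt(m$p[keep]),
               adj_r2 = m$adj_r2)
  })
  do.call(rbind, rows)
}

#' @export
print.longitudinal_fit <- function(x, ...) {
  cat("<longitudinal_fit> paired n = ", x$n, "\n", sep = "")
  print(longitudinal_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.maternal_fit <- function(x, ...) {
  cat("<maternal_fit> paired n = ", x$n, "\n", sep = "")
  print(longitudinal_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}
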