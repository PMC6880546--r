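#' Built-in covariate adjustment sets
#'
#' Each blood collection is residualized on its own covariate set before
#' scoring. Adult and childhood collections adjust for age, sex, BMI and
#' white-blood-cell composition; pregnancy omits sex (all participants
#' female); birth (cord blood) uses gestational age, child sex, birthweight
#' and cord cell composition. The `+smoking` variants add the concurrent
#' smoking indicator and are used in sensitivity reruns.
#'
#' The token `"wbc"` expands at fit time to whichever of the six standard
#' leukocyte proportion columns (`cd8t`, `cd4t`, `nk`, `bcell`, `mono`,
#' `gran`) the covariate table carries.
#'
#' @param name One of `"midlife"`, `"adolescence"`, `"childhood"`,
#'   `"pregnancy"`, `"birth"`, `"midlife+smoking"`, `"adolescence+smoking"`,
#'   or `"none"` (intercept-only: residualization just centres each CpG).
#' @return An `adjustment_set` object (name plus covariate column list).
#' @export
adjustment_set <- function(name) {
  presets <- list(
    "midlife"             = c("age", "sex", "bmi", "wbc"),
    "adolescence"         = c("age", "sex", "bmi", "wbc"),
    "childhood"           = c("age", "sex", "bmi", "wbc"),
    "pregnancy"           = c("age", "bmi", "wbc"),
    "birth"               = c("gestational_age", "sex", "birthweight", "wbc"),
    "midlife+smoking"     = c("age", "sex", "bmi", "wbc", "smoking"),
    "adolescence+smoking" = c("age", "sex", "bmi", "wbc", "smoking"),
    "none"                = character(0)
  )
  if (!name %in% names(presets)) {
    stop("unknown adjustment set '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  structure(list(name = name, columns = presets[[name]]),
            class = "adjustment_set")
}

wbc_columns <- c("cd8t", "cd4t", "nk", "bcell", "mono", "gran")

# Expand an adjustment set against the columns actually present in a
# covariate table; "wbc" becomes the leukocyte proportion columns.
expand_adjustment <- function(adj, covars) {
  if (is.character(adj)) {
    cols <- adj
    nm <- paste(adj, collapse = "+")
  } else if (inherits(adj, "adjustment_set")) {
    cols <- adj$columns
    nm <- adj$name
  } else stop("adj must be an adjustment_set or a character vector")
  if ("wbc" %in% cols) {
    cells <- intersect(wbc_columns, names(covars))
    if (!length(cells)) stop("adjustment set '", nm,
                             "' needs WBC proportion columns (",
                             paste(wbc_columns, collapse = ", "),
                             ") but none are present")
    cols <- c(setdiff(cols, "wbc"), cells)
  }
  missing <- setdiff(cols, names(covars))
  if (length(missing)) {
    stop("covariate table lacks column(s) required by adjustment set '",
         nm, "': ", paste(missing, collapse = ", "))
  }
  list(name = nm, columns = cols)
}

#' Residualize a methylation matrix on covariates
#'
#' Replaces each CpG column with the residuals of an OLS regression of that
#' column on an intercept plus the covariates of the active adjustment set,
#' removing their linear contribution before scoring. Output columns have
#' mean zero and are orthogonal to every adjustment covariate.
#'
#' Samples with missing values in any active covariate are dropped with a
#' message (complete-case analysis). Zero-variance covariates are dropped
#' with a message (they carry no adjustable signal). If the leukocyte
#' proportion columns sum to 1 (compositional closure), the last one is
#' dropped automatically to preserve design rank, with a message. Any
#' remaining rank deficiency is a hard error naming the collinear columns.
#'
#' @param meth Numeric samples-by-CpGs matrix with dimnames.
#' @param covars Data frame with a `sample_id` column plus covariates.
#' @param adj An [adjustment_set()], preset name, or character vector of
#'   covariate column names (may include the token `"wbc"`).
#' @return Residualized matrix (possibly fewer rows after complete-case
#'   filtering), same column order, `time_point` attribute preserved.
#' @export
residualize_matrix <- function(meth, covars, adj) {
  stopifnot(is.matrix(meth), is.data.frame(covars),
            "sample_id" %in% names(covars))
  if (is.character(adj) && length(adj) == 1 && !identical(adj, "wbc") &&
      adj %in% c("midlife", "adolescence", "childhood", "pregnancy",
                 "birth", "midlife+smoking", "adolescence+smoking", "none")) {
    adj <- adjustment_set(adj)
  }
  ex <- expand_adjustment(adj, covars)
  tp <- attr(meth, "time_point")

  ids <- intersect(rownames(meth), covars$sample_id)
  if (!length(ids)) stop("no overlapping sample ids between methylation and covariates")
  cv <- covars[match(ids, covars$sample_id), , drop = FALSE]

  cols <- ex$columns
  if (length(cols)) {
    cc <- stats::complete.cases(cv[, cols, drop = FALSE])
    if (any(!cc)) {
      message(sum(!cc), " sample(s) dropped for missing covariates (",
              ex$name, ")")
      cv <- cv[cc, , drop = FALSE]
      ids <- ids[cc]
    }
  }
  Y <- meth[ids, , drop = FALSE]

  if (!length(cols)) {
    res <- scale(Y, center = TRUE, scale = FALSE)
    attr(res, "scaled:center") <- NULL
    attr(res, "time_point") <- tp
    return(res)
  }

  X <- as.matrix(cv[, cols, drop = FALSE])
  storage.mode(X) <- "double"

  # compositional closure of cell proportions: drop the last cell column
  cells <- intersect(wbc_columns, cols)
  if (length(cells) >= 2) {
    s <- rowSums(X[, cells, drop = FALSE])
    if (max(abs(s - 1)) < 1e-6) {
      message("WBC proportions sum to 1; dropping '", cells[length(cells)],
              "' to preserve design rank")
      X <- X[, setdiff(colnames(X), cells[length(cells)]), drop = FALSE]
    }
  }

  const <- apply(X, 2, function(z) stats::sd(z) == 0 || !is.finite(stats::sd(z)))
  if (any(const)) {
    message("dropping zero-variance covariate(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }

  D <- cbind(`(Intercept)` = 1, X)
  if (nrow(D) <= ncol(D)) {
    stop("too few samples (", nrow(D), ") for ", ncol(D) - 1L,
         " covariates plus intercept")
  }
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    aliased <- colnames(D)[qd$pivot[(qd$rank + 1L):ncol(D)]]
    stop("rank-deficient adjustment design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  res <- qr.resid(qd, Y)
  dimnames(res) <- dimnames(Y)
  attr(res, "time_point") <- tp
  res
}
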