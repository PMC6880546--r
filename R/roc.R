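#' ROC curve and AUC for a score against a binary label
#'
#' AUC is computed in the Mann-Whitney formulation with half credit for
#' ties:
#' \deqn{\mathrm{AUC} = \frac{1}{n_+ n_-} \sum_{i \in +}\sum_{j \in -}
#'   \left([s_i > s_j] + \tfrac{1}{2}[s_i = s_j]\right),}
#' evaluated via midranks. The stored curve is built over all distinct
#' score thresholds (predict positive when score >= threshold), starts at
#' (0, 0), ends at (1, 1), and its trapezoidal area equals the AUC exactly
#' (ties produce diagonal segments). AUC is invariant under strictly
#' monotone transforms of the score.
#'
#' @param score Numeric score vector.
#' @param label Binary label vector (logical, 0/1, or two-level factor);
#'   the higher/`TRUE` level is the positive class.
#' @param contrast Optional label describing the contrast.
#' @return Object of class `roc_result`: list with `contrast`, `auc`,
#'   `n_pos`, `n_neg`, `curve` (data frame `fpr`, `tpr`).
#' @export
roc_auc <- function(score, label, contrast = NULL) {
  score <- as.numeric(score)
  if (is.factor(label)) {
    if (nlevels(droplevels(label)) > 2) stop("label must be binary")
    label <- label == levels(droplevels(label))[2]
  }
  label <- as.logical(label)
  if (length(score) != length(label)) stop("score and label lengths differ")
  keep <- is.finite(score) & !is.na(label)
  score <- score[keep]; label <- label[keep]
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present (n_pos = ", n_pos,
         ", n_neg = ", n_neg, ")")
  }
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # tie-grouped curve over decreasing thresholds
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; l <- label[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[last] / n_neg),
                      tpr = c(0, tp[last] / n_pos))
  structure(list(contrast = contrast, auc = auc,
                 n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "roc_result")
}

#' Trapezoidal area under a stored ROC curve
#' @param roc A `roc_result`.
#' @return Numeric area; equals `roc$auc` up to floating point.
#' @export
roc_trapezoid_area <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  x <- roc$curve$fpr; y <- roc$curve$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result>", if (!is.null(x$contrast)) paste0(" ", x$contrast),
      " AUC = ", sprintf("%.4f", x$auc),
      " (n_pos = ", x$n_pos, ", n_neg = ", x$n_neg, ")\n", sep = "")
  invisible(x)
}
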