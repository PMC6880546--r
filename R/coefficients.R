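#' Load a nested family of CpG coefficient sets
#'
#' Reads a tab-separated coefficient file with columns `cpg`, `weight` and
#' `set` (one row per CpG per set) and returns the family of scoring models
#' it defines. A family is the nested structure used by the DNAm-Alc
#' biomarkers: the CpGs of every smaller set must be a subset of the CpGs of
#' every larger set, while the weights themselves may differ between sets
#' (each set is an independently tuned linear predictor).
#'
#' @param path Path to a TSV file with header columns `cpg`, `weight`, `set`.
#' @return An object of class `coef_family`: a list of `coef_set` objects
#'   ordered from smallest to largest, each with elements `name`, `weights`
#'   (named numeric vector, names are CpG identifiers) and `n_cpgs`.
#' @seealso [default_coefficient_file()] for the bundled synthetic family,
#'   [compute_score()] to apply a set to a methylation matrix.
#' @export
load_coefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", strip.white = TRUE)
  need <- c("cpg", "weight", "set")
  if (!all(need %in% names(raw))) {
    stop("coefficient file must have columns 'cpg', 'weight', 'set'; found: ",
         paste(names(raw), collapse = ", "))
  }
  w <- suppressWarnings(as.numeric(raw$weight))
  bad <- which(is.na(w) | !is.finite(w))
  if (length(bad)) {
    stop("non-numeric or non-finite weight at line ", bad[1] + 1L,
         " of ", path, " (cpg '", raw$cpg[bad[1]], "')")
  }
  if (any(w == 0)) {
    stop("zero weight for cpg '", raw$cpg[which(w == 0)[1]],
         "'; coefficient sets must contain non-zero weights only")
  }
  sets <- split(seq_len(nrow(raw)), raw$set)
  fam <- lapply(names(sets), function(nm) {
    idx <- sets[[nm]]
    cg <- raw$cpg[idx]
    dup <- cg[duplicated(cg)]
    if (length(dup)) {
      stop("duplicate CpG '", dup[1], "' within set '", nm, "'")
    }
    new_coef_set(nm, stats::setNames(w[idx], cg))
  })
  fam <- fam[order(vapply(fam, function(s) s$n_cpgs, integer(1)))]
  validate_nesting(fam)
  structure(fam, class = "coef_family")
}

new_coef_set <- function(name, weights) {
  structure(list(name = name, weights = weights,
                 n_cpgs = length(weights)),
            class = "coef_set")
}

# Nesting: every smaller set's CpGs must appear in every larger set.
validate_nesting <- function(fam) {
  if (length(fam) < 2L) return(invisible(fam))
  for (i in seq_len(length(fam) - 1L)) {
    small <- fam[[i]]
    large <- fam[[i + 1L]]
    missing <- setdiff(names(small$weights), names(large$weights))
    if (length(missing)) {
      stop("nesting violation: CpG '", missing[1], "' of set '", small$name,
           "' is absent from larger set '", large$name, "'")
    }
  }
  invisible(fam)
}

#' Extract one coefficient set from a family
#'
#' @param family A `coef_family` from [load_coefficients()].
#' @param name Set label, e.g. `"dnamalc.144"`.
#' @return A `coef_set`.
#' @export
coefficient_set <- function(family, name) {
  stopifnot(inherits(family, "coef_family"))
  nm <- vapply(family, function(s) s$name, character(1))
  i <- match(name, nm)
  if (is.na(i)) {
    stop("no coefficient set named '", name, "'; available: ",
         paste(nm, collapse = ", "))
  }
  family[[i]]
}

#' Names of the sets in a coefficient family, smallest first
#' @param family A `coef_family`.
#' @return Character vector of set labels.
#' @export
set_names <- function(family) {
  stopifnot(inherits(family, "coef_family"))
  vapply(family, function(s) s$name, character(1))
}

#' Path to the bundled synthetic coefficient family
#'
#' The package ships a synthetic family with the canonical 5/23/78/144
#' nested structure of the published DNAm-Alc models. The weights are
#' simulated stand-ins (lasso-like: many small, few large, mixed sign) so
#' that the full pipeline can run without access-restricted inputs; users
#' holding the real published coefficients supply their own file in the same
#' TSV dialect (`cpg`, `weight`, `set`).
#'
#' @return Path to the installed TSV file.
#' @export
default_coefficient_file <- function() {
  system.file("extdata", "dnamalc_synthetic_coefficients.tsv",
              package = "methalc", mustWork = TRUE)
}

#' @export
print.coef_set <- function(x, ...) {
  cat("<coef_set> ", x$name, ": ", x$n_cpgs, " CpGs, weight range [",
      format(min(x$weights), digits = 3), ", ",
      format(max(x$weights), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' @export
print.coef_family <- function(x, ...) {
  cat("<coef_family> ", length(x), " nested sets: ",
      paste(sprintf("%s (%d)", set_names(x),
                    vapply(x, function(s) s$n_cpgs, integer(1))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
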