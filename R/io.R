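#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits one TSV per collection for methylation (`meth_<tp>.tsv`, first
#' column `sample_id`), covariates (`covariates_<tp>.tsv`) and phenotypes
#' (`phenotypes_<tp>.tsv`), plus the ground-truth sidecar
#' (`ground_truth.tsv`), the configuration (`config.yaml`) and the
#' calibration constants (`calibration.yaml`). The round trip through
#' [read_cohort()] is lossless to full double precision.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!length(cohort$meth) || !nrow(cohort$truth)) {
    stop("refusing to write an empty cohort")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tp in names(cohort$meth)) {
    write_methylation(cohort$meth[[tp]], file.path(dir, paste0("meth_", tp, ".tsv")))
    data.table::fwrite(cohort$covars[[tp]],
                       file.path(dir, paste0("covariates_", tp, ".tsv")),
                       sep = "\t")
  }
  for (tp in names(cohort$pheno)) {
    data.table::fwrite(cohort$pheno[[tp]],
                       file.path(dir, paste0("phenotypes_", tp, ".tsv")),
                       sep = "\t")
  }
  data.table::fwrite(cohort$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t")
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(c(cfg, list(.seed_used = cohort$seed)),
                   file.path(dir, "config.yaml"), precision = 15)
  cal <- cohort$calibration
  cal$true_r2 <- as.list(cal$true_r2)
  yaml::write_yaml(cal, file.path(dir, "calibration.yaml"), precision = 15)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return A `sim_cohort` (without re-deriving latents: truth, config and
#'   calibration come from the sidecar files).
#' @export
read_cohort <- function(dir) {
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  seed_used <- cfgl$.seed_used
  cfgl$.seed_used <- NULL
  cfg <- structure(cfgl, class = "sim_config")
  cfg$avail <- unlist(cfg$avail)
  meth <- list(); covars <- list(); pheno <- list()
  for (f in list.files(dir, pattern = "^meth_.*\\.tsv$")) {
    tp <- sub("^meth_(.*)\\.tsv$", "\\1", f)
    meth[[tp]] <- read_methylation(file.path(dir, f), time_point = tp)
    covars[[tp]] <- as.data.frame(
      data.table::fread(file.path(dir, paste0("covariates_", tp, ".tsv"))))
    pf <- file.path(dir, paste0("phenotypes_", tp, ".tsv"))
    if (file.exists(pf)) pheno[[tp]] <- as.data.frame(data.table::fread(pf))
  }
  cal <- yaml::read_yaml(file.path(dir, "calibration.yaml"))
  cal$true_r2 <- unlist(cal$true_r2)
  truth <- as.data.frame(data.table::fread(file.path(dir, "ground_truth.tsv")))
  structure(list(meth = meth, covars = covars, pheno = pheno, truth = truth,
                 calibration = cal, config = cfg,
                 seed = as.integer(seed_used)),
            class = "sim_cohort")
}

#' Write a methylation matrix as TSV (samples in rows)
#'
#' @param meth Samples-by-CpGs numeric matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(meth, path) {
  stopifnot(is.matrix(meth), !is.null(rownames(meth)))
  dt <- data.table::data.table(sample_id = rownames(meth))
  dt <- cbind(dt, data.table::as.data.table(meth))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a methylation matrix from TSV/CSV
#'
#' Expects samples in rows with the first column holding sample ids and
#' remaining columns CpGs; use `transpose = TRUE` for CpGs-in-rows files.
#'
#' @param path Input file (separator sniffed by `data.table::fread`).
#' @param time_point Optional label stored as the `time_point` attribute.
#' @param transpose Is the file CpGs-by-samples?
#' @return Numeric samples-by-CpGs matrix.
#' @export
read_methylation <- function(path, time_point = NULL, transpose = FALSE) {
  dt <- data.table::fread(path)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  if (transpose) m <- t(m)
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate CpG ids in ", path)
  attr(m, "time_point") <- time_point
  m
}
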