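#' Evaluate all coefficient sets at one collection
#'
#' One cross-sectional evaluation cell of the validation: residualizes the
#' collection's methylation on its adjustment set, derives phenotypes,
#' computes the score for every coefficient set, and reports variance
#' explained (R-squared and adjusted, as fractions) for continuous outcomes
#' plus Mann-Whitney AUCs for the standard binary contrasts (heavy vs
#' non-drinkers, heavy vs light drinkers, AUDIT > 15 vs <= 15). Contrasts
#' with an empty class are skipped with a warning and listed in the result.
#'
#' @param meth Raw beta-value matrix for the collection.
#' @param covars Covariate table (`sample_id` + adjustment columns).
#' @param pheno Phenotype table (`sample_id`, frequency/quantity, `audit`).
#' @param family `coef_family` of score models.
#' @param adj Adjustment set (preset name, [adjustment_set()] or columns).
#' @param time_point Label used in the output tables.
#' @return List of class `tp_evaluation`: `r2_table`, `auc_table`,
#'   `scores` (per set), `pheno` (derived), `n`, `skipped_contrasts`.
#' @export
evaluate_timepoint <- function(meth, covars, pheno, family, adj,
                               time_point = attr(meth, "time_point")) {
  if (is.null(time_point)) time_point <- "unspecified"
  resid <- residualize_matrix(meth, covars, adj)
  ph <- derive_phenotypes(pheno, covars)
  ph <- ph[ph$sample_id %in% rownames(resid), , drop = FALSE]
  outcomes <- list(intake = stats::setNames(ph$log_intake, ph$sample_id),
                   audit = stats::setNames(as.numeric(ph$audit), ph$sample_id))
  scores <- lapply(seq_along(family), function(i)
    compute_score(resid, family[[i]]))
  names(scores) <- set_names(family)

  r2_rows <- list()
  for (oc in names(outcomes)) {
    for (s in names(scores)) {
      fit <- variance_explained(scores[[s]], outcomes[[oc]])
      r2_rows[[length(r2_rows) + 1L]] <-
        data.frame(outcome = oc, time_point = time_point, set = s,
                   n = fit$n, r2 = fit$r2, adj_r2 = fit$adj_r2)
    }
  }
  r2_table <- do.call(rbind, r2_rows)
  r2_table$r2_pct <- 100 * r2_table$r2
  r2_table$adj_r2_pct <- 100 * r2_table$adj_r2

  contrasts <- list(
    heavy_vs_non   = list(pos = "heavy", neg = "non"),
    heavy_vs_light = list(pos = "heavy", neg = "light"),
    audit_high     = NULL
  )
  auc_rows <- list(); skipped <- character(0)
  for (cn in names(contrasts)) {
    if (cn == "audit_high") {
      lab <- stats::setNames(ph$audit_high, ph$sample_id)
      use <- names(lab)
    } else {
      cc <- contrasts[[cn]]
      sel <- ph$category %in% c(cc$pos, cc$neg)
      lab <- stats::setNames(ph$category[sel] == cc$pos, ph$sample_id[sel])
      use <- names(lab)
    }
    if (sum(lab) == 0 || sum(!lab) == 0) {
      warning("contrast '", cn, "' skipped at ", time_point,
              ": a class is empty")
      skipped <- c(skipped, cn)
      next
    }
    for (s in names(scores)) {
      ids <- intersect(names(scores[[s]]), use)
      r <- roc_auc(scores[[s]][ids], lab[ids], contrast = cn)
      auc_rows[[length(auc_rows) + 1L]] <-
        data.frame(contrast = cn, time_point = time_point, set = s,
                   n_pos = r$n_pos, n_neg = r$n_neg, auc = r$auc)
    }
  }
  auc_table <- if (length(auc_rows)) do.call(rbind, auc_rows) else
    data.frame(contrast = character(), time_point = character(),
               set = character(), n_pos = integer(), n_neg = integer(),
               auc = numeric())
  structure(list(r2_table = r2_table, auc_table = auc_table,
                 scores = scores, pheno = ph, n = nrow(resid),
                 skipped_contrasts = skipped, time_point = time_point),
            class = "tp_evaluation")
}

#' Sensitivity rerun of a collection's evaluation
#'
#' Re-executes residualize, score and evaluate for one collection under a
#' modified condition: `"exclude_nondrinkers"` drops self-reported
#' never-drinkers before residualization, `"adjust_smoking"` switches to
#' the `+smoking` adjustment set (a constant smoking column is dropped by
#' the residualizer, reducing to the primary run).
#'
#' @param meth,covars,pheno,family,adj,time_point As
#'   [evaluate_timepoint()].
#' @param mode `"exclude_nondrinkers"` or `"adjust_smoking"`.
#' @return A `tp_evaluation` with a `mode` element.
#' @export
sensitivity_rerun <- function(meth, covars, pheno, family, adj,
                              mode = c("exclude_nondrinkers", "adjust_smoking"),
                              time_point = attr(meth, "time_point")) {
  mode <- match.arg(mode)
  force(time_point)  # resolve before meth is subset below
  if (mode == "exclude_nondrinkers") {
    ph <- derive_phenotypes(pheno, covars)
    keep <- ph$sample_id[ph$category != "non"]
    meth <- meth[rownames(meth) %in% keep, , drop = FALSE]
    attr(meth, "time_point") <- time_point
    pheno <- pheno[pheno$sample_id %in% keep, , drop = FALSE]
  } else {
    nm <- if (inherits(adj, "adjustment_set")) adj$name else
      paste(adj, collapse = "+")
    adj <- if (nm %in% c("midlife", "adolescence")) {
      adjustment_set(paste0(nm, "+smoking"))
    } else {
      cols <- if (inherits(adj, "adjustment_set")) adj$columns else adj
      union(cols, "smoking")
    }
  }
  out <- evaluate_timepoint(meth, covars, pheno, family, adj,
                            time_point = time_point)
  out$mode <- mode
  out
}

# family key from generator sample ids ("fam00001_p" -> "fam00001")
family_key <- function(ids) sub("_[po]$", "", ids)

#' Run the full validation pipeline on a (simulated) cohort
#'
#' Orchestrates the whole analysis from one configuration: simulate (or
#' accept) a cohort; per outcome collection (parents at midlife, offspring
#' at adolescence) residualize, score and evaluate variance explained and
#' AUCs for every coefficient set; run the earlier-versus-concurrent
#' longitudinal regressions (pregnancy vs midlife for mothers; childhood
#' and birth vs adolescence for offspring, plus the maternal-pregnancy
#' extension); run sensitivity variants; and write the report tables and a
#' run manifest. Deterministic given the seed.
#'
#' @param config List with elements `sim` (a [sim_config()]) or `cohort`
#'   (a `sim_cohort`); optional `coef_file`, `score_set`, `out_dir`,
#'   `sensitivity` (character subset of the two modes), `seed`.
#' @return List of class `validation_report`: `r2_table`, `auc_table`,
#'   `longitudinal_table`, `sensitivity` (named list of tables),
#'   `longitudinal_fits`, `evaluations`, `manifest`. Written as TSV/YAML
#'   under `out_dir` when given; partial outputs are removed on error.
#' @export
run_validation <- function(config) {
  seed <- if (!is.null(config$seed)) config$seed else 1L
  set.seed(seed)
  cohort <- if (!is.null(config$cohort)) config$cohort else
    simulate_cohort(config$sim, seed = seed)
  coef_file <- if (!is.null(config$coef_file)) config$coef_file else
    cohort$config$coef_file
  family <- load_coefficients(coef_file)
  score_set <- if (!is.null(config$score_set)) config$score_set else
    cohort$config$score_set
  sens_modes <- if (!is.null(config$sensitivity)) config$sensitivity else
    c("exclude_nondrinkers", "adjust_smoking")

  adj_for <- function(tp) adjustment_set(tp)
  outcome_tps <- intersect(c("midlife", "adolescence"), names(cohort$pheno))
  if (!length(outcome_tps)) stop("pipeline stage 'evaluate': no collection ",
                                 "with phenotypes available")

  evals <- list(); sens <- list()
  for (tp in outcome_tps) {
    evals[[tp]] <- evaluate_timepoint(cohort$meth[[tp]], cohort$covars[[tp]],
                                      cohort$pheno[[tp]], family,
                                      adj_for(tp), time_point = tp)
    for (m in sens_modes) {
      sens[[paste(tp, m, sep = ".")]] <-
        sensitivity_rerun(cohort$meth[[tp]], cohort$covars[[tp]],
                          cohort$pheno[[tp]], family, adj_for(tp),
                          mode = m, time_point = tp)
    }
  }
  r2_table <- do.call(rbind, lapply(evals, `[[`, "r2_table"))
  auc_table <- do.call(rbind, lapply(evals, `[[`, "auc_table"))
  rownames(r2_table) <- rownames(auc_table) <- NULL

  # --- longitudinal designs on the reference set's scores ---
  ref <- coefficient_set(family, score_set)
  score_at <- function(tp) {
    res <- residualize_matrix(cohort$meth[[tp]], cohort$covars[[tp]],
                              adj_for(tp))
    s <- compute_score(res, ref)
    stats::setNames(as.numeric(s), family_key(names(s)))
  }
  long_fits <- list(); long_rows <- list()
  add_long <- function(fit, dep, early_lab) {
    tab <- longitudinal_table(fit, dependent = dep)
    long_rows[[length(long_rows) + 1L]] <<- tab
    fit
  }
  audit_of <- function(tp) {
    ph <- cohort$pheno[[tp]]
    stats::setNames(as.numeric(ph$audit), family_key(ph$sample_id))
  }
  designs <- list(
    list(dep = "AUDIT at midlife", out = "midlife", early = "pregnancy",
         conc = "midlife"),
    list(dep = "AUDIT at adolescence", out = "adolescence",
         early = "childhood", conc = "adolescence"),
    list(dep = "AUDIT at adolescence", out = "adolescence",
         early = "birth", conc = "adolescence")
  )
  for (d in designs) {
    if (!all(c(d$early, d$conc) %in% names(cohort$meth)) ||
        !d$out %in% names(cohort$pheno)) next
    fit <- early_vs_concurrent(audit_of(d$out), score_at(d$early),
                               score_at(d$conc),
                               labels = c(d$early, d$conc))
    long_fits[[paste(d$early, d$conc, sep = "_vs_")]] <-
      add_long(fit, d$dep)
  }
  if (all(c("birth", "pregnancy", "adolescence") %in% names(cohort$meth)) &&
      "adolescence" %in% names(cohort$pheno)) {
    fit <- birth_maternal_extension(audit_of("adolescence"),
                                    score_at("birth"), score_at("pregnancy"),
                                    score_concurrent = score_at("adolescence"))
    long_fits$maternal_extension <- add_long(fit, "AUDIT at adolescence")
  }
  longitudinal_tab <- if (length(long_rows)) do.call(rbind, long_rows) else NULL
  if (!is.null(longitudinal_tab)) rownames(longitudinal_tab) <- NULL

  sens_tables <- lapply(sens, function(e)
    list(r2_table = e$r2_table, auc_table = e$auc_table))

  manifest <- list(
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("methalc")),
    effect_mode = cohort$config$effect_mode,
    target_r2 = cohort$config$target_r2,
    n_by_time_point = lapply(cohort$meth, nrow),
    evaluated_n = lapply(evals, `[[`, "n"),
    skipped_contrasts = lapply(evals, `[[`, "skipped_contrasts"),
    sensitivity_modes = sens_modes
  )

  report <- structure(list(r2_table = r2_table, auc_table = auc_table,
                           longitudinal_table = longitudinal_tab,
                           sensitivity = sens_tables,
                           longitudinal_fits = long_fits,
                           evaluations = evals, manifest = manifest),
                      class = "validation_report")

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

#' Write a validation report bundle as TSV + YAML
#'
#' Emits `r2_table.tsv`, `auc_table.tsv`, `longitudinal_table.tsv`,
#' one pair of tables per sensitivity variant, and `manifest.yaml`.
#' Partial outputs are removed if any write fails.
#'
#' @param report A `validation_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name) {
    p <- file.path(dir, name)
    data.table::fwrite(obj, p, sep = "\t")
    written <<- c(written, p)
  }
  tryCatch({
    emit(report$r2_table, "r2_table.tsv")
    emit(report$auc_table, "auc_table.tsv")
    if (!is.null(report$longitudinal_table)) {
      emit(report$longitudinal_table, "longitudinal_table.tsv")
    }
    for (nm in names(report$sensitivity)) {
      emit(report$sensitivity[[nm]]$r2_table,
           paste0("sensitivity_", nm, "_r2.tsv"))
      emit(report$sensitivity[[nm]]$auc_table,
           paste0("sensitivity_", nm, "_auc.tsv"))
    }
    yaml::write_yaml(report$manifest, file.path(dir, "manifest.yaml"))
    written <- c(written, file.path(dir, "manifest.yaml"))
  }, error = function(e) {
    unlink(written)
    stop("report writing failed (partial outputs removed): ",
         conditionMessage(e))
  })
  invisible(dir)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n\nVariance explained (%):\n")
  t1 <- x$r2_table
  t1$adj_r2_pct <- round(t1$adj_r2_pct, 2)
  print(t1[, c("outcome", "time_point", "set", "n", "adj_r2_pct")],
        row.names = FALSE)
  cat("\nAUCs:\n")
  t2 <- x$auc_table
  t2$auc <- round(t2$auc, 3)
  print(t2, row.names = FALSE)
  if (!is.null(x$longitudinal_table)) {
    cat("\nEarlier vs concurrent (standardized scores):\n")
    print(x$longitudinal_table, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
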