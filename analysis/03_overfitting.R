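#!/usr/bin/env Rscript
# Quantifies the overfitting that inflates in-sample evaluations of
# re-estimated CpG coefficients, contrasting (i) the fixed-coefficient
# score, (ii) the in-sample refit of the same CpGs, and (iii) the refit's
# 5-fold out-of-fold performance — on the default cohort and on pure-noise
# CpGs where the truth is exactly zero.

suppressMessages(library(methalc))
set.seed(1)

fam <- load_coefficients(default_coefficient_file())
ref <- coefficient_set(fam, "dnamalc.144")

co <- simulate_cohort(sim_config(), seed = 1)
resid_mid <- suppressMessages(
  residualize_matrix(co$meth$midlife, co$covars$midlife, "midlife"))
ph <- derive_phenotypes(co$pheno$midlife, co$covars$midlife)
y <- setNames(ph$log_intake, ph$sample_id)

rc <- refit_comparison(resid_mid, co$covars$midlife, y,
                       cpgs = names(ref$weights))
fixed <- variance_explained(compute_score(resid_mid, ref), y)

ids <- intersect(rownames(resid_mid), names(y))
oof <- crossval_r2(as.numeric(y[ids]),
                   resid_mid[ids, names(ref$weights)], k = 5)

noise_gap <- replicate(20, {
  M <- matrix(rnorm(500 * 144), 500)
  yy <- rnorm(500)
  fit_ols(yy, M)$r2 - crossval_r2(yy, M, k = 5)
})

tab <- data.frame(
  model = c("fixed_coefficient_score_adj_r2",
            "covariates_only_adj_r2",
            "in_sample_refit_adj_r2",
            "in_sample_refit_unadjusted_r2",
            "refit_out_of_fold_r2",
            "pure_noise_refit_gap_mean"),
  value = c(fixed$adj_r2, rc$covariates_only$adj_r2, rc$refit$adj_r2,
            rc$refit$r2, oof, mean(noise_gap)))
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/03_overfitting.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf(
  "Key finding: refitting the 144 CpGs in-sample reports %.1f%% adjusted R2\nagainst %.1f%% for the fixed-coefficient score on identical data — the\nin-sample refit roughly doubles apparent performance. Out-of-fold the refit\ndrops to %.1f%%, and on pure-noise CpGs the in-sample vs out-of-fold gap is\n%.2f R2 units. -> results/03_overfitting.tsv\n",
  100 * rc$refit$adj_r2, 100 * fixed$adj_r2, 100 * oof, mean(noise_gap)))
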