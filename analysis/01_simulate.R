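#!/usr/bin/env Rscript
# Simulates the default two-generation cohort emulation (cumulative-exposure
# mode, ~1049 parents / 626 adolescents, target midlife score-intake
# adjusted R2 of 7.6%) and writes the full cohort under scratch/ (large)
# plus a compact summary under results/.

suppressMessages(library(methalc))

cfg <- sim_config()  # the documented default study conditions
cohort <- simulate_cohort(cfg, seed = 1)
print(cohort)

write_cohort(cohort, "scratch/cohort_default")
cat("full cohort written to scratch/cohort_default\n")

dir.create("results", showWarnings = FALSE)
mix <- implied_drinker_mixture(cfg)
cat("\nImplied drinker mixture (fractions):\n"); print(round(mix, 4))

summary_tab <- data.frame(
  quantity = c("n_midlife", "n_pregnancy", "n_adolescence", "n_childhood",
               "n_birth", "signal_amplitude_kappa",
               paste0("true_r2_", names(cohort$calibration$true_r2))),
  value = c(vapply(c("midlife", "pregnancy", "adolescence", "childhood",
                     "birth"), function(tp) nrow(cohort$meth[[tp]]),
                   numeric(1)),
            cohort$calibration$kappa,
            unname(cohort$calibration$true_r2)))
write.table(summary_tab, "results/01_cohort_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nKey finding: the closed-form calibration places the 144-CpG score at",
    sprintf("a true R2 of %.4f against midlife log intake,",
            cohort$calibration$true_r2[["dnamalc.144"]]),
    "\nwith the smaller nested sets ordered below it -> results/01_cohort_summary.tsv\n")
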