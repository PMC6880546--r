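test_that("configs validate their invariants", {
  expect_error(sim_config(target_r2 = 1), "target_r2")
  expect_error(sim_config(p_nondrinker = 1), "p_nondrinker")
  expect_error(sim_config(sigma_cpg = 0), "sigma_cpg")
  expect_error(sim_config(n_families = 0), "n_families")
  expect_error(sim_config(baseline_range = c(0.7, 0.3)), "baseline_range")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("infeasible targets fail fast with the feasible bound", {
  cfg <- fast_config(effect_mode = "genetic_stable", target_r2 = 0.9,
                     n_families = 50)
  expect_error(simulate_cohort(cfg, seed = 1), "feasible bound")
})

test_that("identical config and seed give identical cohorts", {
  cfg <- fast_config(n_families = 60, effect_mode = "exposure_concurrent",
                     target_r2 = 0.05)
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_identical(a$meth, b$meth)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth, b$truth)
  d <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(a$meth$midlife, d$meth$midlife))
})

test_that("raw beta values stay strictly inside (0, 1)", {
  cfg <- sim_config(n_families = 80, background_cpgs = 20)
  co <- simulate_cohort(cfg, seed = 2)
  for (tp in names(co$meth)) {
    expect_true(all(co$meth[[tp]] > 0 & co$meth[[tp]] < 1))
  }
})

test_that("phenotypes respect their bounds and the non-drinker floor", {
  cfg <- sim_config(n_families = 400, background_cpgs = 0)
  co <- simulate_cohort(cfg, seed = 3)
  for (tp in names(co$pheno)) {
    ph <- derive_phenotypes(co$pheno[[tp]], co$covars[[tp]])
    expect_true(all(ph$audit >= 0 & ph$audit <= 40))
    expect_true(all(ph$intake_gday >= 0))
    expect_true(all(ph$audit[ph$intake_gday == 0] == 0))
    expect_equal(ph$log_intake, log(ph$intake_gday + 1))
  }
  mix <- implied_drinker_mixture(cfg)
  expect_equal(rowSums(mix), c(female = 1, male = 1), tolerance = 1e-12)
  # observed category mixture tracks the implied one loosely
  ph <- derive_phenotypes(co$pheno$midlife, co$covars$midlife)
  expect_lt(abs(mean(ph$category == "non") - cfg$p_nondrinker), 0.03)
})

test_that("stable-mode scores persist across time while concurrent-mode do not", {
  fam <- load_coefficients(default_coefficient_file())
  ref <- coefficient_set(fam, "dnamalc.144")
  xtime_cor <- function(mode, seed) {
    cfg <- fast_config(effect_mode = mode, target_r2 = 0.076,
                       n_families = 500)
    co <- simulate_cohort(cfg, seed = seed)
    sc <- function(tp) {
      r <- suppressMessages(residualize_matrix(co$meth[[tp]],
                                               co$covars[[tp]], tp))
      s <- compute_score(r, ref)
      setNames(as.numeric(s), sub("_p$", "", names(s)))
    }
    sp <- sc("pregnancy"); sm <- sc("midlife")
    ids <- intersect(names(sp), names(sm))
    cor(sp[ids], sm[ids])
  }
  expect_gt(xtime_cor("genetic_stable", 21), 0.8)
  expect_lt(abs(xtime_cor("exposure_concurrent", 22)), 0.15)
})

test_that("the stored closed-form R2 is ordered and hits the target at the top", {
  cfg <- fast_config(effect_mode = "exposure_concurrent", target_r2 = 0.08)
  co <- simulate_cohort(cfg, seed = 4)
  tr <- co$calibration$true_r2
  expect_equal(unname(tr["dnamalc.144"]), 0.08, tolerance = 1e-6)
  expect_true(all(diff(tr) > 0))  # more CpGs, more signal
})

test_that("cohorts round-trip losslessly through the TSV writer", {
  cfg <- sim_config(n_families = 40, background_cpgs = 5)
  co <- simulate_cohort(cfg, seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (tp in names(co$meth)) {
    expect_equal(back$meth[[tp]], co$meth[[tp]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(back$pheno$midlife$audit, co$pheno$midlife$audit)
  expect_equal(back$calibration$kappa, co$calibration$kappa,
               tolerance = 1e-12)
  expect_equal(back$config$target_r2, co$config$target_r2)
  # refuse empty cohorts
  empty <- co; empty$meth <- list()
  expect_error(write_cohort(empty, withr::local_tempdir()), "empty cohort")
})

test_that("written file row counts match the configured cohort flow", {
  cfg <- sim_config(n_families = 1018, background_cpgs = 0)
  co <- simulate_cohort(cfg, seed = 12)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  nrows <- function(f) nrow(data.table::fread(file.path(dir, f)))
  expect_equal(nrows("meth_midlife.tsv"), 1018)
  expect_equal(nrows("meth_pregnancy.tsv"), sum(co$truth$sex_parent == 1))
  expect_equal(nrows("meth_adolescence.tsv"), round(626 / 1049 * 1018))
  expect_equal(nrows("meth_childhood.tsv"), round(601 / 1049 * 1018))
  expect_equal(nrows("meth_birth.tsv"), round(438 / 1049 * 1018))
  expect_equal(nrows("phenotypes_midlife.tsv"), 1018)
  expect_equal(nrows("ground_truth.tsv"), 1018)
})

test_that("null mode produces score-outcome associations centred at zero", {
  fam <- load_coefficients(default_coefficient_file())
  ref <- coefficient_set(fam, "dnamalc.144")
  cfg <- fast_config(effect_mode = "null", parent_times = "midlife",
                     n_families = 400)
  adj <- replicate(60, {
    co <- simulate_cohort(cfg, seed = sample.int(1e6, 1))
    r <- suppressMessages(residualize_matrix(co$meth$midlife,
                                             co$covars$midlife, "midlife"))
    s <- compute_score(r, ref)
    ph <- derive_phenotypes(co$pheno$midlife, co$covars$midlife)
    variance_explained(s, setNames(ph$log_intake, ph$sample_id))$adj_r2
  })
  expect_lt(abs(mean(adj)), 0.003)
})
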