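test_that("fit_ols handles perfect, degenerate and oracle-checked designs", {
  x <- 1:10
  f <- fit_ols(x, x)
  expect_equal(f$beta[2], 1)
  expect_equal(f$r2, 1)
  expect_equal(f$adj_r2, 1)

  expect_error(fit_ols(rnorm(10), rep(3, 10)), "collinear")
  expect_error(fit_ols(rnorm(4), matrix(rnorm(12), 4)), "too few")

  # fixed 12-point dataset against the hand-rolled normal-equations oracle
  set.seed(30)
  X <- cbind(a = rnorm(12), b = runif(12))
  y <- 1 + 0.5 * X[, 1] - 2 * X[, 2] + rnorm(12, 0, 0.3)
  fit <- fit_ols(y, X)
  orc <- oracle_ols(y, X)
  expect_equal(fit$beta, unname(orc$beta), tolerance = 1e-8)
  expect_equal(fit$se, unname(orc$se), tolerance = 1e-8)
  expect_equal(fit$p, unname(orc$p), tolerance = 1e-8)
  expect_equal(fit$adj_r2, orc$adj_r2, tolerance = 1e-10)
  expect_true(fit$adj_r2 <= fit$r2)
})

test_that("single-predictor R2 equals squared Pearson correlation", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(50); y <- 0.3 * x + rnorm(50)
    expect_equal(fit_ols(y, x)$r2, cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("variance_explained recovers affine relations and null signals", {
  set.seed(32)
  s <- rnorm(100)
  expect_equal(variance_explained(s, 2 * s + 3)$r2, 1)
  # null: adjusted R2 distribution centred at zero
  adj <- replicate(300, {
    variance_explained(rnorm(400), rnorm(400))$adj_r2
  })
  expect_lt(abs(mean(adj)), 0.002)
  # name-based alignment: same per-sample relation, shuffled order
  sc <- setNames(rnorm(30), paste0("s", 1:30))
  perm <- sample(30)
  oc <- setNames(2 * as.numeric(sc)[perm] + 1, names(sc)[perm])
  expect_equal(variance_explained(sc, oc)$r2, 1)
})

test_that("roc_auc matches forced cases and its own stored curve", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(2, 10), rbinom(10, 1, 0.5) * 0 + c(rep(0, 5), rep(1, 5)))$auc, 0.5)
  set.seed(33)
  for (i in 1:20) {
    s <- sample(1:8, 40, replace = TRUE)  # heavy ties
    l <- rbinom(40, 1, 0.4)
    if (sum(l) == 0 || sum(l) == 40) next
    r <- roc_auc(s, l)
    expect_equal(r$auc, oracle_auc(s, as.logical(l)))
    expect_equal(roc_trapezoid_area(r), r$auc, tolerance = 1e-12)
    expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
    expect_equal(tail(r$curve$fpr, 1), 1); expect_equal(tail(r$curve$tpr, 1), 1)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under monotone transforms and flips on negation", {
  set.seed(34)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  a <- roc_auc(s, l)$auc
  expect_equal(roc_auc(exp(s), l)$auc, a)
  expect_equal(roc_auc(5 * s - 2, l)$auc, a)
  expect_equal(roc_auc(-s, l)$auc, 1 - a)  # continuous scores: no ties
})

test_that("roc_auc agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(35)
  for (i in 1:25) {
    s <- round(rnorm(50), 1)  # some ties
    l <- rbinom(50, 1, 0.5)
    if (sum(l) %in% c(0, 50)) next
    expect_equal(roc_auc(s, l)$auc,
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("refit comparison reports both fits and refuses p >= n", {
  set.seed(36)
  n <- 120
  M <- rand_meth(n, paste0("cg", 1:10), beta_scale = FALSE)
  cv <- data.frame(sample_id = rownames(M), age = rnorm(n, 50, 5),
                   sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 25, 4))
  y <- setNames(rnorm(n), rownames(M))
  rc <- refit_comparison(M, cv, y)
  expect_s3_class(rc$covariates_only, "ols_fit")
  expect_s3_class(rc$refit, "ols_fit")
  expect_equal(rc$refit$df_model, 13)
  expect_gte(rc$refit$r2, rc$covariates_only$r2)
  expect_error(refit_comparison(M[1:12, ], cv[1:12, ], y[1:12]),
               "parameter count")
})

test_that("in-sample refit R2 dominates any fixed-weight score (span property)", {
  set.seed(37)
  fam <- load_coefficients(default_coefficient_file())
  cs <- coefficient_set(fam, "dnamalc.5")
  for (i in 1:10) {
    n <- 80
    M <- rand_meth(n, names(cs$weights), beta_scale = FALSE)
    cv <- data.frame(sample_id = rownames(M), age = rnorm(n, 50, 5),
                     sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 25, 4))
    y <- setNames(rnorm(n), rownames(M))
    rc <- refit_comparison(M, cv, y)
    fixed <- as.numeric(compute_score(M, cs))
    fixed_fit <- fit_ols(as.numeric(y),
                         cbind(age = cv$age, sex = cv$sex, bmi = cv$bmi,
                               score = fixed))
    expect_gte(rc$refit$r2, fixed_fit$r2 - 1e-12)
  }
})

test_that("cross-validated R2 exposes the overfit of pure-noise refits", {
  set.seed(38)
  n <- 300
  X <- matrix(rnorm(n * 40), n)
  y <- rnorm(n)
  ins <- fit_ols(y, X)$r2
  oof <- crossval_r2(y, X, k = 5)
  expect_gt(ins, oof)
  expect_gt(ins, 0.05)  # ~p/n by construction
})

test_that("sensitivity reruns reduce to the primary run in degenerate cases", {
  cfg <- fast_config(effect_mode = "exposure_concurrent", target_r2 = 0.05,
                     n_families = 300, p_nondrinker = 0)
  co <- simulate_cohort(cfg, seed = 5)
  fam <- load_coefficients(default_coefficient_file())
  suppressMessages(suppressWarnings({
    prim <- evaluate_timepoint(co$meth$midlife, co$covars$midlife,
                               co$pheno$midlife, fam, "midlife")
    # no non-drinkers simulated -> exclusion is a no-op
    sens <- sensitivity_rerun(co$meth$midlife, co$covars$midlife,
                              co$pheno$midlife, fam, "midlife",
                              mode = "exclude_nondrinkers")
  }))
  expect_equal(sens$r2_table[, c("r2", "adj_r2")],
               prim$r2_table[, c("r2", "adj_r2")], tolerance = 1e-12)
  # constant smoking column -> +smoking adjustment equals primary
  co$covars$midlife$smoking <- 1L
  suppressMessages(suppressWarnings({
    prim2 <- evaluate_timepoint(co$meth$midlife, co$covars$midlife,
                                co$pheno$midlife, fam, "midlife")
    sens2 <- sensitivity_rerun(co$meth$midlife, co$covars$midlife,
                               co$pheno$midlife, fam, "midlife",
                               mode = "adjust_smoking")
  }))
  expect_equal(sens2$r2_table$adj_r2, prim2$r2_table$adj_r2,
               tolerance = 1e-12)
})

test_that("smoking adjustment moves R2 against the injected confounding", {
  cfg <- fast_config(effect_mode = "smoking_confounded", target_r2 = 0.05,
                     smoking_effect = 0.3, n_families = 800)
  co <- simulate_cohort(cfg, seed = 6)
  fam <- load_coefficients(default_coefficient_file())
  suppressMessages(suppressWarnings({
    prim <- evaluate_timepoint(co$meth$midlife, co$covars$midlife,
                               co$pheno$midlife, fam, "midlife")
    adj <- sensitivity_rerun(co$meth$midlife, co$covars$midlife,
                             co$pheno$midlife, fam, "midlife",
                             mode = "adjust_smoking")
  }))
  pick <- function(t) t$adj_r2[t$outcome == "intake" & t$set == "dnamalc.144"]
  # smoking inflates the unadjusted association; adjusting removes it
  expect_gt(pick(prim$r2_table), pick(adj$r2_table))
})
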