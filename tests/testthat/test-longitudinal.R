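named <- function(x, ids = sprintf("f%03d", seq_along(x))) setNames(x, ids)

test_that("joint coefficients equal single-predictor ones on orthogonal scores", {
  set.seed(50)
  n <- 200
  e <- rnorm(n)
  c_ <- rnorm(n)
  c_ <- residuals(lm(c_ ~ e))          # exactly orthogonalized
  y <- 0.8 * c_ + rnorm(n)
  ids <- sprintf("f%03d", 1:n)
  fit <- early_vs_concurrent(named(y, ids), named(e, ids), named(c_, ids),
                             standardize = FALSE)
  expect_equal(fit$models$joint$beta[2], fit$models$early$beta[2],
               tolerance = 1e-8)
  expect_equal(fit$models$joint$beta[3], fit$models$concurrent$beta[2],
               tolerance = 1e-8)
})

test_that("degenerate longitudinal inputs are rejected", {
  set.seed(51)
  s <- named(rnorm(50))
  y <- named(rnorm(50))
  expect_error(early_vs_concurrent(y, s, s), "collinear")
  expect_error(early_vs_concurrent(y, named(rep(1, 50)), named(rnorm(50))),
               "zero variance")
  expect_error(early_vs_concurrent(y[1:8], s[1:8], named(rnorm(50))[1:8]),
               "n > 10")
})

test_that("concurrent-only signal yields the concurrent-strong/early-null pattern", {
  set.seed(52)
  nsim <- 120; n <- 400
  p_early <- p_conc <- b_early <- numeric(nsim)
  cover <- logical(nsim)
  beta_true <- 0.5
  for (i in seq_len(nsim)) {
    e <- rnorm(n); c_ <- rnorm(n)
    y <- beta_true * c_ + rnorm(n)
    ids <- sprintf("f%03d", seq_len(n))
    fit <- early_vs_concurrent(named(y, ids), named(e, ids), named(c_, ids),
                               standardize = FALSE)
    j <- fit$models$joint
    b_early[i] <- j$beta[2]
    p_early[i] <- j$p[2]; p_conc[i] <- j$p[3]
    ci <- j$beta[2] + c(-1, 1) * qt(0.975, n - 3) * j$se[2]
    cover[i] <- ci[1] <= 0 && ci[2] >= 0
  }
  expect_lt(median(p_conc), 1e-6)
  expect_gt(median(p_early), 0.2)
  expect_lt(abs(mean(b_early)), 0.02)
  # 95% CI for the null early effect covers 0 at the nominal rate
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("a stable shared component gives the early score real power", {
  set.seed(53)
  cfg <- fast_config(effect_mode = "genetic_stable", target_r2 = 0.076,
                     n_families = 600)
  co <- simulate_cohort(cfg, seed = 53)
  fam <- load_coefficients(default_coefficient_file())
  ref <- coefficient_set(fam, cfg$score_set)
  sc <- function(tp) {
    r <- suppressMessages(residualize_matrix(co$meth[[tp]],
                                             co$covars[[tp]], tp))
    s <- compute_score(r, ref)
    setNames(as.numeric(s), sub("_p$", "", names(s)))
  }
  ph <- derive_phenotypes(co$pheno$midlife, co$covars$midlife)
  aud <- setNames(as.numeric(ph$audit), sub("_p$", "", ph$sample_id))
  fit <- early_vs_concurrent(aud, sc("pregnancy"), sc("midlife"),
                             labels = c("pregnancy", "midlife"))
  expect_lt(fit$models$early$p[2], 0.01)
  # and the two scores are strongly correlated across ~21 years
  ids <- intersect(names(sc("pregnancy")), names(sc("midlife")))
  expect_gt(cor(sc("pregnancy")[ids], sc("midlife")[ids]), 0.8)
})

test_that("maternal extension fits singles and joints with pair dropping", {
  set.seed(54)
  n <- 150
  ids <- sprintf("f%03d", 1:n)
  q <- rnorm(n)                       # prenatal latent
  birth <- q + 0.5 * rnorm(n)         # birth score carries it
  maternal <- q + 0.5 * rnorm(n)      # so does the maternal score
  adol <- rnorm(n)
  y <- 0.8 * q + rnorm(n)             # outcome driven by the latent only
  expect_message(
    fit <- birth_maternal_extension(named(y, ids), named(birth, ids)[1:120],
                                    named(maternal, ids),
                                    named(adol, ids)),
    "unpaired")
  expect_equal(fit$n, 120)
  expect_named(fit$models,
               c("birth", "maternal", "joint", "joint_concurrent"))
  # both single fits detect the shared latent; joint fits attenuate both
  expect_lt(fit$models$birth$p[2], 0.01)
  expect_lt(fit$models$maternal$p[2], 0.01)
  expect_lt(abs(fit$models$joint$beta[2]), abs(fit$models$birth$beta[2]))
  expect_lt(abs(fit$models$joint$beta[3]), abs(fit$models$maternal$beta[2]))
  expect_error(birth_maternal_extension(named(y, ids), named(rep(1, n), ids),
                                        named(maternal, ids)),
               "zero-variance")
})

test_that("an independent maternal score shows a null effect at nominal rate", {
  set.seed(55)
  nsim <- 100; n <- 250
  cover <- logical(nsim)
  for (i in seq_len(nsim)) {
    ids <- sprintf("f%03d", 1:n)
    birth <- rnorm(n); maternal <- rnorm(n)
    y <- 0.4 * birth + rnorm(n)
    fit <- birth_maternal_extension(named(y, ids), named(birth, ids),
                                    named(maternal, ids),
                                    standardize = FALSE)
    m <- fit$models$maternal
    ci <- m$beta[2] + c(-1, 1) * qt(0.975, m$n - 2) * m$se[2]
    cover[i] <- ci[1] <= 0 && ci[2] >= 0
  }
  expect_gt(mean(cover), 0.88)
})

test_that("longitudinal tables use the fixed report schema", {
  set.seed(56)
  n <- 100; ids <- sprintf("f%03d", 1:n)
  fit <- early_vs_concurrent(named(rnorm(n), ids), named(rnorm(n), ids),
                             named(rnorm(n), ids),
                             labels = c("pregnancy", "midlife"))
  tab <- longitudinal_table(fit, dependent = "AUDIT at midlife")
  expect_equal(names(tab),
               c("dependent", "independent", "n", "beta", "se", "p", "adj_r2"))
  expect_equal(tab$independent,
               c("pregnancy", "midlife", "pregnancy + midlife"))
  expect_equal(tab$n, rep(n, 3))
})
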