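#' Configuration for the synthetic two-generation methylation cohort
#'
#' The generator emulates a two-generation longitudinal cohort: one parent
#' and one offspring per family, parents sampled at pregnancy (females
#' only) and midlife (~21 years later), offspring at birth, childhood and
#' adolescence. Methylation is simulated on the logit scale (baseline +
#' signal + covariate effects + noise) and inverse-logit transformed, so
#' raw beta values always lie in (0, 1). Alcohol intake is a zero-inflated
#' log-normal (a point mass of never-drinkers plus a log-normal positive
#' part), AUDIT a noisy monotone function of long-run intake floored at 0
#' for non-drinkers and capped at 40.
#'
#' The alcohol signal placed at the score CpGs is governed by
#' `effect_mode`:
#' \describe{
#'   \item{`exposure_concurrent`}{methylation tracks drinking at the
#'     concurrent collection only; drinking is independent across time
#'     points. Earlier collections carry no alcohol signal.}
#'   \item{`exposure_cumulative`}{methylation tracks a stable drinking
#'     propensity with amplitude growing with years of exposure,
#'     \eqn{d(T) = T/(T + \tau)}; concurrent intake is a noisy expression
#'     of the same propensity. Collections before drinking onset (birth,
#'     childhood) and the pregnancy collection (abstinence plus signal
#'     decay within gestation) carry no signal.}
#'   \item{`genetic_stable`}{methylation tracks a stable per-person
#'     component \eqn{g_i} at every collection including birth, and
#'     drinking is partly driven by the same component - the genetic
#'     confounding alternative the longitudinal design must detect.}
#'   \item{`smoking_confounded`}{as `exposure_concurrent`, plus a smoking
#'     effect on the score CpGs with smoking positively correlated with
#'     drinking, so unadjusted scores are confounded and the `+smoking`
#'     adjustment sets remove the distortion.}
#'   \item{`null`}{no alcohol signal anywhere.}
#' }
#'
#' Effect sizes are specified as a target score-outcome R-squared (for the
#' largest coefficient set, against log intake at the reference time point)
#' and converted internally to a logit-scale amplitude by closed-form
#' moment calculations; see [simulate_cohort()].
#'
#' @param n_families Families (one parent + one offspring each).
#' @param p_female_parent Fraction of parents that are mothers (mothers
#'   additionally have the pregnancy collection).
#' @param cohorts Which generations to simulate (`"parents"`,
#'   `"offspring"`).
#' @param parent_times,offspring_times Collections to generate.
#' @param avail Named availability fractions for offspring collections
#'   (birth, childhood, adolescence); adolescence also limits who has
#'   phenotypes.
#' @param coef_file Coefficient TSV (default: bundled synthetic family).
#' @param score_set Reference set for signal placement and calibration
#'   (default the largest, `"dnamalc.144"`).
#' @param background_cpgs Number of signal-free background CpGs.
#' @param effect_mode See above.
#' @param target_r2 Target score-outcome R-squared in \[0, 1).
#' @param stable_share `genetic_stable` only: stable-component share of
#'   score variance (drives cross-time score correlation).
#' @param propensity_weight `exposure_cumulative` only: share of concurrent
#'   intake variance coming from the stable propensity.
#' @param duration_halflife \eqn{\tau} (years) of the cumulative amplitude.
#' @param onset_age Age (years) drinking begins.
#' @param p_nondrinker Never-drinker fraction.
#' @param intake_mean_gday Overall mean intake in g/day (zeros included).
#' @param intake_sdlog sdlog of the positive log-normal part.
#' @param audit_intercept,audit_slope,audit_sd AUDIT generation:
#'   `audit = round(clamp(a0 + a1 * log(long-run intake + 1) + noise))`.
#' @param sigma_cpg Per-CpG logit-scale noise SD.
#' @param baseline_range Range of per-CpG baseline beta means.
#' @param covariate_effect_sd SD of per-CpG covariate effects (logit units
#'   per SD of covariate).
#' @param smoking_effect,smoking_drinking_cor,p_smoker Smoking-confounded
#'   mode parameters.
#' @param prenatal_effect,prenatal_birth_amp,maternal_pregnancy_amp
#'   Optional prenatal-exposure extension: a per-family latent affecting
#'   offspring adolescent AUDIT, offspring birth methylation and maternal
#'   pregnancy methylation respectively (all default 0 = off).
#' @param seed Default seed used by [simulate_cohort()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 1049,
                       p_female_parent = 518 / 1049,
                       cohorts = c("parents", "offspring"),
                       parent_times = c("pregnancy", "midlife"),
                       offspring_times = c("birth", "childhood", "adolescence"),
                       avail = c(birth = 438 / 1049, childhood = 601 / 1049,
                                 adolescence = 626 / 1049),
                       coef_file = default_coefficient_file(),
                       score_set = "dnamalc.144",
                       background_cpgs = 100,
                       effect_mode = c("exposure_cumulative",
                                       "exposure_concurrent",
                                       "genetic_stable",
                                       "smoking_confounded", "null"),
                       target_r2 = 0.076,
                       stable_share = 0.85,
                       propensity_weight = 0.5,
                       duration_halflife = 10,
                       onset_age = 15,
                       p_nondrinker = 0.05,
                       intake_mean_gday = 8.2,
                       intake_sdlog = 0.8,
                       audit_intercept = 2.86,
                       audit_slope = 2.8,
                       audit_sd = 3,
                       sigma_cpg = 0.3,
                       baseline_range = c(0.3, 0.7),
                       covariate_effect_sd = 0.05,
                       smoking_effect = 0.1,
                       smoking_drinking_cor = 0.5,
                       p_smoker = 0.2,
                       prenatal_effect = 0,
                       prenatal_birth_amp = 0,
                       maternal_pregnancy_amp = 0,
                       seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  cohorts <- match.arg(cohorts, several.ok = TRUE)
  stopifnot(n_families >= 1, p_female_parent >= 0, p_female_parent <= 1,
            background_cpgs >= 0,
            target_r2 >= 0, target_r2 < 1,
            stable_share > 0, stable_share < 1,
            propensity_weight > 0, propensity_weight <= 1,
            duration_halflife > 0,
            p_nondrinker >= 0, p_nondrinker < 1,
            intake_mean_gday > 0, intake_sdlog > 0,
            audit_sd > 0, sigma_cpg > 0,
            length(baseline_range) == 2,
            baseline_range[1] > 0, baseline_range[2] < 1,
            baseline_range[1] < baseline_range[2],
            covariate_effect_sd >= 0,
            p_smoker > 0, p_smoker < 1,
            abs(smoking_drinking_cor) < 1)
  cfg <- list(n_families = as.integer(n_families),
              p_female_parent = p_female_parent,
              cohorts = cohorts,
              parent_times = parent_times,
              offspring_times = offspring_times,
              avail = avail,
              coef_file = coef_file, score_set = score_set,
              background_cpgs = as.integer(background_cpgs),
              effect_mode = effect_mode, target_r2 = target_r2,
              stable_share = stable_share,
              propensity_weight = propensity_weight,
              duration_halflife = duration_halflife, onset_age = onset_age,
              p_nondrinker = p_nondrinker,
              intake_mean_gday = intake_mean_gday,
              intake_sdlog = intake_sdlog,
              audit_intercept = audit_intercept, audit_slope = audit_slope,
              audit_sd = audit_sd,
              sigma_cpg = sigma_cpg, baseline_range = baseline_range,
              covariate_effect_sd = covariate_effect_sd,
              smoking_effect = smoking_effect,
              smoking_drinking_cor = smoking_drinking_cor,
              p_smoker = p_smoker,
              prenatal_effect = prenatal_effect,
              prenatal_birth_amp = prenatal_birth_amp,
              maternal_pregnancy_amp = maternal_pregnancy_amp,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# positive-part meanlog implied by the overall mean intake
.intake_meanlog <- function(cfg) {
  log(cfg$intake_mean_gday / (1 - cfg$p_nondrinker)) - cfg$intake_sdlog^2 / 2
}

# Zero-inflated log-normal intake as a monotone transform of a standard
# normal latent u: the lowest p_nondrinker quantiles map to 0, the rest to
# the matching log-normal quantile.
intake_from_latent <- function(u, cfg) {
  ml <- .intake_meanlog(cfg)
  F <- stats::pnorm(u)
  out <- numeric(length(u))
  pos <- F > cfg$p_nondrinker
  Fp <- pmin((F[pos] - cfg$p_nondrinker) / (1 - cfg$p_nondrinker), 1 - 1e-12)
  out[pos] <- stats::qlnorm(Fp, meanlog = ml, sdlog = cfg$intake_sdlog)
  out
}

# Moments of h(u) = log(intake(u) + 1) for u ~ N(0,1), by adaptive
# quadrature on the smooth positive branch (h = 0 below the never-drinker
# threshold).
.h_moments <- function(cfg) {
  ml <- .intake_meanlog(cfg)
  z0 <- stats::qnorm(cfg$p_nondrinker)
  h <- function(u) {
    F <- pmin((stats::pnorm(u) - cfg$p_nondrinker) / (1 - cfg$p_nondrinker),
              1 - 1e-12)
    log1p(stats::qlnorm(F, ml, cfg$intake_sdlog))
  }
  q <- function(f) stats::integrate(function(u) f(u) * stats::dnorm(u),
                                    lower = z0, upper = 12,
                                    rel.tol = 1e-10, abs.tol = 1e-12)$value
  Eh <- q(h)
  Eh2 <- q(function(u) h(u)^2)
  Euh <- q(function(u) u * h(u))
  list(Eh = Eh, Vh = Eh2 - Eh^2, Cuh = Euh)
}

# Gauss-Hermite moments of the inverse-logit transform:
# m1 = E sigma(mu + tau Z), m2 = E sigma^2, m1p = E sigma'(mu + tau Z).
.gh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussHermite(48)
    cache
  }
})

.sigmoid_moments <- function(mu, tau) {
  gh <- .gh()
  z <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  # l = mu_j + tau_j * z_k over (cpg j, node k)
  L <- sweep(outer(tau, z, "*"), 1, mu, "+")
  S <- stats::plogis(L)
  m1 <- drop(S %*% w)
  m2 <- drop(S^2 %*% w)
  m1p <- drop((S * (1 - S)) %*% w)
  list(m1 = m1, m2 = m2, m1p = m1p)
}

# Exact correlation matrix of standardized Dirichlet cell proportions.
.cell_alpha <- c(cd8t = 2.5, cd4t = 4.25, nk = 1, bcell = 1.5,
                 mono = 2, gran = 13.75)

.cell_cor <- function(alpha = .cell_alpha) {
  a0 <- sum(alpha)
  V <- alpha * (a0 - alpha) / (a0^2 * (a0 + 1))
  C <- -outer(alpha, alpha) / (a0^2 * (a0 + 1))
  diag(C) <- V
  stats::cov2cor(C)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

# Per-CpG variance of the covariate contribution on the logit scale, given
# the effect matrix C (cpgs x covariate slots, all slots standardized to
# unit variance; cell slots are mutually correlated).
.covariate_logit_var <- function(C, cell_cols) {
  other <- setdiff(colnames(C), cell_cols)
  v <- rowSums(C[, other, drop = FALSE]^2)
  R <- .cell_cor()[cell_cols, cell_cols]
  Cc <- C[, cell_cols, drop = FALSE]
  v + rowSums((Cc %*% R) * Cc)
}

# Solve the logit-scale signal amplitude kappa (and, for genetic mode, the
# drinking heritability r) so that the reference-set score attains the
# target R-squared against log intake at the reference time point.
# Closed-form: with signal l = mu0 + kappa*d*sgn(b)*z + covariates + noise
# and z, noise jointly Gaussian, Stein's lemma gives the beta-scale slope
# kappa*d*E[sigma'(l)] per CpG, and Gauss-Hermite quadrature the residual
# variance of sigma(l).
calibrate_signal <- function(cfg, b, mu0_logit, Vc_ref, d_ref, hm) {
  sgn <- sign(b)
  Vy <- hm$Vh
  czy_base <- hm$Cuh
  czy <- switch(cfg$effect_mode,
                exposure_concurrent = czy_base,
                smoking_confounded = czy_base,
                exposure_cumulative = sqrt(cfg$propensity_weight) * czy_base,
                genetic_stable = czy_base,  # scaled by sqrt(r) later
                null = czy_base)
  KV <- function(kappa) {
    tau2 <- (kappa * d_ref)^2 + Vc_ref + cfg$sigma_cpg^2
    mm <- .sigmoid_moments(mu0_logit, sqrt(tau2))
    slope <- kappa * d_ref * mm$m1p
    v <- pmax(mm$m2 - mm$m1^2 - mm$m1p^2 * ((kappa * d_ref)^2 + Vc_ref),
              1e-14)
    list(K = sum(abs(b) * slope), V = sum(b^2 * v), mm = mm, v = v,
         slope = slope)
  }
  share <- function(kappa) {
    kv <- KV(kappa)
    kv$K^2 / (kv$K^2 + kv$V)
  }
  if (cfg$effect_mode == "null" || cfg$target_r2 == 0) {
    kv <- KV(0)
    return(list(kappa = 0, r = NA_real_, KV = kv, czy = czy, Vy = Vy,
                ceiling = 0))
  }
  # amplitudes beyond kappa_cap saturate the inverse-logit; the quadrature
  # is accurate well past the whole solving region (tau <~ 1)
  kappa_cap <- 8
  if (cfg$effect_mode == "genetic_stable") {
    f <- function(k) share(k) - cfg$stable_share
    hi <- 1
    while (f(hi) < 0 && hi < kappa_cap) hi <- min(hi * 2, kappa_cap)
    if (f(hi) < 0) stop("cannot reach stable_share ", cfg$stable_share,
                        "; maximum attainable is ", signif(share(hi), 4))
    kappa <- stats::uniroot(f, c(1e-8, hi), tol = 1e-12)$root
    max_r2 <- cfg$stable_share * czy_base^2 / Vy
    if (cfg$target_r2 >= max_r2) {
      stop("target_r2 ", cfg$target_r2, " infeasible in genetic_stable ",
           "mode; feasible bound is ", signif(max_r2, 4),
           " at stable_share ", cfg$stable_share)
    }
    r <- cfg$target_r2 / max_r2
    return(list(kappa = kappa, r = r, KV = KV(kappa),
                czy = sqrt(r) * czy_base, Vy = Vy, ceiling = max_r2))
  }
  r2_of <- function(kappa) {
    kv <- KV(kappa)
    (kv$K * czy)^2 / ((kv$K^2 + kv$V) * Vy)
  }
  ceiling_r2 <- r2_of(kappa_cap)
  if (cfg$target_r2 >= ceiling_r2) {
    stop("target_r2 ", cfg$target_r2, " infeasible under mode '",
         cfg$effect_mode, "'; feasible bound is ", signif(ceiling_r2, 4))
  }
  f <- function(k) r2_of(k) - cfg$target_r2
  hi <- 1
  while (f(hi) < 0 && hi < kappa_cap) hi <- min(hi * 2, kappa_cap)
  kappa <- stats::uniroot(f, c(1e-10, hi), tol = 1e-14)$root
  list(kappa = kappa, r = NA_real_, KV = KV(kappa), czy = czy, Vy = Vy,
       ceiling = ceiling_r2)
}

# Closed-form true score-outcome R-squared for each coefficient set, at the
# reference time point, given the calibrated amplitude.
.true_r2_by_set <- function(family, ref, cal, cfg, mu0_logit, Vc_ref, d_ref) {
  sgn_ref <- sign(ref$weights)
  tau2 <- (cal$kappa * d_ref)^2 + Vc_ref + cfg$sigma_cpg^2
  mm <- .sigmoid_moments(mu0_logit, sqrt(tau2))
  slope <- cal$kappa * d_ref * mm$m1p
  v <- pmax(mm$m2 - mm$m1^2 - mm$m1p^2 * ((cal$kappa * d_ref)^2 + Vc_ref),
            1e-14)
  names(slope) <- names(v) <- names(sgn_ref) <- names(ref$weights)
  out <- vapply(family, function(s) {
    cg <- names(s$weights)
    K <- sum(s$weights * sgn_ref[cg] * slope[cg])
    V <- sum(s$weights^2 * v[cg])
    (K * cal$czy)^2 / ((K^2 + V) * cal$Vy)
  }, numeric(1))
  stats::setNames(out, set_names(family))
}

#' Simulate a two-generation longitudinal methylation cohort
#'
#' Generates methylation matrices, covariate tables and phenotype tables
#' per collection, with full ground truth (latent stable components,
#' drinking latents, calibration constants and the closed-form true
#' score-outcome R-squared per coefficient set). Fully reproducible from
#' the seed. See [sim_config()] for the model.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return Object of class `sim_cohort`: list with `meth`, `covars`,
#'   `pheno` (named lists by time point), `truth` (per-family data frame),
#'   `calibration`, `config`, `seed`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(seed)

  fam <- load_coefficients(cfg$coef_file)
  ref <- coefficient_set(fam, cfg$score_set)
  b <- ref$weights
  sgn <- sign(b)
  J <- length(b)
  nbg <- cfg$background_cpgs
  cpg_ids <- c(names(b), if (nbg) sprintf("cgbg%05d", seq_len(nbg)))
  nC <- length(cpg_ids)

  mu_beta <- stats::runif(nC, cfg$baseline_range[1], cfg$baseline_range[2])
  mu0 <- stats::qlogis(mu_beta)

  cov_slots <- c("age", "sex", "bmi", names(.cell_alpha))
  C <- matrix(stats::rnorm(nC * length(cov_slots), 0, cfg$covariate_effect_sd),
              nrow = nC, dimnames = list(cpg_ids, cov_slots))
  Vc <- .covariate_logit_var(C, names(.cell_alpha))
  Vc_ref <- Vc[seq_len(J)]
  if (cfg$effect_mode == "smoking_confounded") {
    # the smoking effect is removable by the +smoking adjustment sets, so
    # it counts as covariate variance for calibration purposes
    Vc_ref <- Vc_ref + cfg$smoking_effect^2  # unit-variance standardized smoke
  }

  hm <- .h_moments(cfg)
  ages <- list(midlife = c(50.2, 5.4), pregnancy_gap = 21.1,
               adolescence = c(17.4, 0.9), childhood = c(7.4, 0.1))
  d_ref <- switch(cfg$effect_mode,
                  exposure_cumulative = {
                    T_ref <- ages$midlife[1] - cfg$onset_age
                    T_ref / (T_ref + cfg$duration_halflife)
                  },
                  1)
  cal <- calibrate_signal(cfg, b, mu0[seq_len(J)], Vc_ref, d_ref, hm)
  true_r2 <- .true_r2_by_set(fam, ref, cal, cfg, mu0[seq_len(J)], Vc_ref,
                             d_ref)

  n <- cfg$n_families
  fid <- sprintf("fam%05d", seq_len(n))

  # --- family latents (drawn for both generations regardless of cohorts,
  #     to keep the latent layer identical across cohort subsets) ---
  g_p <- stats::rnorm(n); g_o <- stats::rnorm(n)
  P_p <- stats::rnorm(n); P_o <- stats::rnorm(n)
  q_fam <- stats::rnorm(n)
  sex_parent <- stats::rbinom(n, 1, cfg$p_female_parent)  # 1 = female
  sex_off <- stats::rbinom(n, 1, 0.5)
  age_mid <- stats::rnorm(n, ages$midlife[1], ages$midlife[2])
  age_adol <- stats::rnorm(n, ages$adolescence[1], ages$adolescence[2])
  age_child <- stats::rnorm(n, ages$childhood[1], ages$childhood[2])

  drinking_latent <- function(P, g, eps) {
    switch(cfg$effect_mode,
           exposure_cumulative = sqrt(cfg$propensity_weight) * P +
             sqrt(1 - cfg$propensity_weight) * eps,
           genetic_stable = sqrt(cal$r) * g + sqrt(1 - cal$r) * eps,
           eps)  # concurrent / smoking / null: occasion-specific
  }
  u_mid <- drinking_latent(P_p, g_p, stats::rnorm(n))
  u_adol <- drinking_latent(P_o, g_o, stats::rnorm(n))

  # methylation driver z and amplitude d per (generation, time point)
  driver <- function(gen, tp, age) {
    mode <- cfg$effect_mode
    z <- numeric(n); d <- 0
    if (mode == "genetic_stable") {
      z <- if (gen == "parents") g_p else g_o
      d <- 1
    } else if (mode %in% c("exposure_concurrent", "smoking_confounded")) {
      if (gen == "parents" && tp == "midlife") { z <- u_mid; d <- 1 }
      if (gen == "offspring" && tp == "adolescence") { z <- u_adol; d <- 1 }
    } else if (mode == "exposure_cumulative") {
      if (gen == "parents" && tp == "midlife") {
        T_ <- mean(age) - cfg$onset_age
        z <- P_p; d <- T_ / (T_ + cfg$duration_halflife)
      }
      if (gen == "offspring" && tp == "adolescence") {
        T_ <- max(mean(age) - cfg$onset_age, 0)
        z <- P_o; d <- T_ / (T_ + cfg$duration_halflife)
      }
    }
    list(z = z, d = d)
  }

  smoke_from <- function(u, p) {
    rho <- cfg$smoking_drinking_cor
    lat <- rho * u + sqrt(1 - rho^2) * stats::rnorm(length(u))
    as.integer(lat > stats::qnorm(1 - p))
  }

  std <- function(x, m, s) if (s == 0) rep(0, length(x)) else (x - m) / s
  std_bin <- function(x, p) std(x, p, sqrt(p * (1 - p)))

  make_tp <- function(gen, tp, keep, sample_id) {
    nk <- sum(keep)
    cells <- .rdirichlet(nk, .cell_alpha)
    cm <- .cell_alpha / sum(.cell_alpha)
    a0 <- sum(.cell_alpha)
    cs <- sqrt(.cell_alpha * (a0 - .cell_alpha) / (a0^2 * (a0 + 1)))
    if (gen == "parents") {
      if (tp == "midlife") {
        age <- age_mid[keep]; sex <- sex_parent[keep]
        bmi <- stats::rnorm(nk, 25.5, 4)
        smoke <- smoke_from(u_mid[keep], cfg$p_smoker)
        cov <- data.frame(sample_id = sample_id, age = age, sex = sex,
                          bmi = bmi, smoking = smoke, cells,
                          check.names = FALSE)
        Xs <- cbind(age = std(age, ages$midlife[1], ages$midlife[2]),
                    sex = std_bin(sex, cfg$p_female_parent),
                    bmi = std(bmi, 25.5, 4),
                    sweep(sweep(cells, 2, cm), 2, cs, "/"))
      } else { # pregnancy
        age <- age_mid[keep] - ages$pregnancy_gap
        bmi <- stats::rnorm(nk, 24, 3.5)
        cov <- data.frame(sample_id = sample_id, age = age, bmi = bmi,
                          cells, check.names = FALSE)
        Xs <- cbind(age = std(age, ages$midlife[1] - ages$pregnancy_gap,
                              ages$midlife[2]),
                    sex = 0,
                    bmi = std(bmi, 24, 3.5),
                    sweep(sweep(cells, 2, cm), 2, cs, "/"))
        smoke <- NULL
      }
    } else {
      sex <- sex_off[keep]
      sex_s <- std_bin(sex, 0.5)
      if (tp == "adolescence") {
        age <- age_adol[keep]
        bmi <- stats::rnorm(nk, 22, 3.5)
        smoke <- smoke_from(u_adol[keep], 0.3)
        cov <- data.frame(sample_id = sample_id, age = age, sex = sex,
                          bmi = bmi, smoking = smoke, cells,
                          check.names = FALSE)
        Xs <- cbind(age = std(age, ages$adolescence[1], ages$adolescence[2]),
                    sex = sex_s, bmi = std(bmi, 22, 3.5),
                    sweep(sweep(cells, 2, cm), 2, cs, "/"))
      } else if (tp == "childhood") {
        age <- age_child[keep]
        bmi <- stats::rnorm(nk, 16.5, 2)
        cov <- data.frame(sample_id = sample_id, age = age, sex = sex,
                          bmi = bmi, cells, check.names = FALSE)
        Xs <- cbind(age = std(age, ages$childhood[1], ages$childhood[2]),
                    sex = sex_s, bmi = std(bmi, 16.5, 2),
                    sweep(sweep(cells, 2, cm), 2, cs, "/"))
        smoke <- NULL
      } else { # birth
        age <- NULL
        ga <- stats::rnorm(nk, 39.5, 1.5)
        bw <- stats::rnorm(nk, 3450, 450)
        cov <- data.frame(sample_id = sample_id, gestational_age = ga,
                          sex = sex, birthweight = bw, cells,
                          check.names = FALSE)
        Xs <- cbind(age = std(ga, 39.5, 1.5), sex = sex_s,
                    bmi = std(bw, 3450, 450),
                    sweep(sweep(cells, 2, cm), 2, cs, "/"))
        smoke <- NULL
      }
    }
    drv <- driver(gen, tp, if (gen == "parents" && tp == "midlife") age_mid
                  else if (gen == "offspring" && tp == "adolescence") age_adol
                  else 0)
    L <- matrix(mu0, nrow = nk, ncol = nC, byrow = TRUE)
    if (drv$d > 0 && cal$kappa > 0) {
      L[, seq_len(J)] <- L[, seq_len(J)] +
        (cal$kappa * drv$d) * outer(drv$z[keep], sgn)
    }
    if (cfg$effect_mode == "smoking_confounded" && !is.null(smoke)) {
      L[, seq_len(J)] <- L[, seq_len(J)] +
        cfg$smoking_effect * outer(std_bin(smoke, cfg$p_smoker), sgn)
    }
    if (cfg$prenatal_birth_amp != 0 && gen == "offspring" && tp == "birth") {
      L[, seq_len(J)] <- L[, seq_len(J)] +
        cfg$prenatal_birth_amp * outer(q_fam[keep], sgn)
    }
    if (cfg$maternal_pregnancy_amp != 0 && gen == "parents" &&
        tp == "pregnancy") {
      L[, seq_len(J)] <- L[, seq_len(J)] +
        cfg$maternal_pregnancy_amp * outer(q_fam[keep], sgn)
    }
    L <- L + Xs %*% t(C) +
      matrix(stats::rnorm(nk * nC, 0, cfg$sigma_cpg), nrow = nk)
    beta <- stats::plogis(L)
    dimnames(beta) <- list(sample_id, cpg_ids)
    attr(beta, "time_point") <- tp
    list(meth = beta, covars = cov)
  }

  make_pheno <- function(u, keep, sample_id, u_long) {
    nk <- sum(keep)
    intake <- intake_from_latent(u[keep], cfg)
    quantity <- sample(1:4, nk, replace = TRUE)
    freq <- ifelse(intake > 0, intake * 7 / (8 * quantity), 0)
    h_long <- log1p(intake_from_latent(u_long[keep], cfg))
    audit_star <- cfg$audit_intercept + cfg$audit_slope * h_long +
      stats::rnorm(nk, 0, cfg$audit_sd)
    if (cfg$prenatal_effect != 0) {
      audit_star <- audit_star + cfg$prenatal_effect * q_fam[keep]
    }
    audit <- ifelse(intake == 0, 0L,
                    as.integer(pmin(40, pmax(0, round(audit_star)))))
    data.frame(sample_id = sample_id, freq_per_week = freq,
               quantity_units = quantity, audit = audit)
  }

  meth <- list(); covars <- list(); pheno <- list()

  if ("parents" %in% cfg$cohorts) {
    pid <- paste0(fid, "_p")
    if ("pregnancy" %in% cfg$parent_times) {
      keep <- sex_parent == 1
      r <- make_tp("parents", "pregnancy", keep, pid[keep])
      meth$pregnancy <- r$meth; covars$pregnancy <- r$covars
    }
    if ("midlife" %in% cfg$parent_times) {
      keep <- rep(TRUE, n)
      r <- make_tp("parents", "midlife", keep, pid)
      meth$midlife <- r$meth; covars$midlife <- r$covars
      u_long <- switch(cfg$effect_mode, exposure_cumulative = P_p, u_mid)
      pheno$midlife <- make_pheno(u_mid, keep, pid, u_long)
    }
  }
  if ("offspring" %in% cfg$cohorts) {
    oid <- paste0(fid, "_o")
    for (tp in intersect(cfg$offspring_times,
                         c("birth", "childhood", "adolescence"))) {
      n_tp <- round(cfg$avail[[tp]] * n)
      keep <- rep(FALSE, n)
      keep[sample(n, n_tp)] <- TRUE
      r <- make_tp("offspring", tp, keep, oid[keep])
      meth[[tp]] <- r$meth; covars[[tp]] <- r$covars
      if (tp == "adolescence") {
        u_long <- switch(cfg$effect_mode, exposure_cumulative = P_o, u_adol)
        pheno$adolescence <- make_pheno(u_adol, keep, oid[keep], u_long)
      }
    }
  }

  truth <- data.frame(family = fid,
                      sex_parent = sex_parent, sex_offspring = sex_off,
                      g_parent = g_p, g_offspring = g_o,
                      propensity_parent = P_p, propensity_offspring = P_o,
                      u_midlife = u_mid, u_adolescence = u_adol,
                      prenatal = q_fam)

  structure(list(meth = meth, covars = covars, pheno = pheno,
                 truth = truth,
                 calibration = list(kappa = cal$kappa, r = cal$r,
                                    ceiling_r2 = cal$ceiling,
                                    true_r2 = true_r2,
                                    target_r2 = cfg$target_r2,
                                    cov_zy = cal$czy, var_y = cal$Vy),
                 config = cfg, seed = as.integer(seed)),
            class = "sim_cohort")
}

#' Implied drinker-category mixture of a configuration
#'
#' The zero-inflated log-normal intake model implies, per sex, the
#' non/light/at-risk/heavy fractions under the standard thresholds.
#'
#' @param config A [sim_config()].
#' @return Matrix (2 x 4) of fractions, rows `female`, `male`.
#' @export
implied_drinker_mixture <- function(config) {
  ml <- .intake_meanlog(config)
  sl <- config$intake_sdlog
  p0 <- config$p_nondrinker
  pl <- function(x) stats::plnorm(x, ml, sl)
  mk <- function(lo, hi) c(non = p0,
                           light = (1 - p0) * pl(lo),
                           at_risk = (1 - p0) * (pl(hi) - pl(lo)),
                           heavy = (1 - p0) * (1 - pl(hi)))
  rbind(female = mk(14, 28), male = mk(28, 42))
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> mode = ", x$config$effect_mode,
      ", seed = ", x$seed, "\n", sep = "")
  for (tp in names(x$meth)) {
    cat("  ", tp, ": ", nrow(x$meth[[tp]]), " samples x ",
        ncol(x$meth[[tp]]), " CpGs\n", sep = "")
  }
  cat("  true R2 by set (reference outcome): ",
      paste(sprintf("%s=%.4f", names(x$calibration$true_r2),
                    x$calibration$true_r2), collapse = ", "), "\n", sep = "")
  invisible(x)
}
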