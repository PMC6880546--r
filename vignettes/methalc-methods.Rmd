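---
title: "Methods: models, calibration and design choices in methalc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in methalc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(methalc)
```

## The biomarker model

A DNAm-Alc score is a pure weighted sum over a fixed CpG panel,
$S_s = \sum_i \beta_i\, m_{s,i}$, with no intercept. The published family
comprises four nested sets (5, 23, 78, 144 CpGs); each set is its own
tuned predictor, so shared CpGs may carry different weights in different
sets, but the CpG membership is nested. `load_coefficients()` enforces the
nesting, uniqueness and finite non-zero weights at load time, failing with
the offending CpG and line.

Because the score has no intercept, its absolute location is arbitrary.
Every downstream quantity used here — R², adjusted R², OLS slopes on
standardized scores, Mann–Whitney AUC — is invariant to location (and, for
AUC, to any strictly monotone transform), so this is documented rather
than "fixed". Users comparing against other implementations should check
whether those add an intercept or scaling; this one deliberately does not.

Missing coefficient CpGs (the realistic failure mode when 450K-trained
panels meet EPIC arrays) are governed by `missing_policy`: hard error
(default), drop-with-warning above a coverage floor (default 0.95), or
impute-zero, which is only meaningful on residualized input where zero is
the covariate-predicted mean.

## Residualization

Each collection's methylation is residualized per CpG on an intercept plus
that collection's adjustment set (`adjustment_set()`): age, sex, BMI and
six Houseman-style leukocyte proportions for adult/childhood blood;
gestational age, sex, birthweight and cord cell proportions at birth; no
sex at pregnancy. Cell proportions that sum to one are rank-deficient with
an intercept, so the last proportion column is dropped automatically (the
span is unchanged). Zero-variance covariates are dropped with a message —
this makes the smoking sensitivity rerun reduce exactly to the primary
analysis when smoking is constant — while any remaining collinearity is a
hard error naming the columns. Samples missing any active covariate are
removed complete-case with a logged count. Residualization is performed
within each collection separately, each on its own covariates.

Two exact linear-algebra facts are exploited as cross-checks in the test
suite: residualizing twice is a no-op, and scoring commutes with
residualization (the score of residualized methylation equals the
residual of the scores).

## Alcohol phenotypes

Intake in grammes of ethanol per day is frequency × quantity × 8 / 7
(8 g per UK unit, units/week to g/day). Questionnaire frequency categories
map to occasions/week through a declared midpoint convention
(`frequency_midpoints()`: never = 0, monthly or less = 0.25, 2–4/month =
0.75, 2–4/week = 3, ≥4/week = 5) — cohort derivations rarely publish their
mapping, so this one is explicit and overridable, and "never" forces zero
regardless of reported quantity. Intake is modelled as
$\log(\text{g/day} + 1)$ (natural log). Drinker categories use the
sex-specific thresholds — women: light (0, 14], at-risk (14, 28), heavy
≥ 28 g/day; men: light (0, 28], at-risk (28, 42), heavy ≥ 42 — with the
unambiguous heavy thresholds taking precedence at boundaries (the interval
notation in the source questionnaire conventions is garbled; these
resolutions keep the categories exhaustive and mutually exclusive, which
is property-tested over a boundary-dense grid). AUDIT (0–40) is
dichotomized strictly above 15.

## Evaluation

OLS fits use QR with an intercept always included; adjusted R² is
$1-(1-R^2)(n-1)/(n-p-1)$ and may be negative (reported as-is). P-values
are nominal two-sided t tests; no multiplicity correction is applied,
matching standard practice for this kind of validation report.
Percentages are fractions × 100, rounded only at presentation.

AUC uses the Mann–Whitney formulation with half-credit ties, computed via
midranks; the stored ROC curve is built over distinct thresholds so its
trapezoidal area equals the AUC to machine precision (ties appear as
diagonal segments). This is exactly testable against an $O(n^2)$ pairwise
enumeration and against pROC, both of which the test suite does.

The overfitting contrast refits the panel's CpGs (plus age, sex, BMI) by
OLS in the evaluation sample. Because the fixed-weight score lies in the
column span of the refit design, the refit's in-sample R² dominates the
fixed score's on any data — an exact property asserted on every fixture.
The honest comparison is adjusted R² and k-fold out-of-fold R²
(`crossval_r2()`); with 144 pure-noise CpGs at n = 500 the in-sample vs
out-of-fold gap is close to one R² unit while the fixed score shows none
beyond the ~1/n sampling scale.

## The earlier-versus-concurrent design

`early_vs_concurrent()` fits three models of a later outcome (AUDIT):
earlier score alone, concurrent score alone, both jointly, on the
complete-case paired subsample. Scores are standardized to unit variance
within the paired subsample by default so coefficients are per SD and
comparable across simulations; a raw-scale option exists because the
original report's coefficient scale is not stated. Identical early and
concurrent vectors (|r| ≈ 1) are rejected as collinear.
`birth_maternal_extension()` applies the same machinery to offspring birth
scores and maternal pregnancy scores against the offspring's adolescent
outcome.

## The synthetic cohort generator

The generator formalizes the latent quantities the validation reasons
about: a stable per-person component $g_i$, a drinking propensity $P_i$,
occasion-level drinking latents $u_i(t)$, and an optional prenatal
exposure latent per family.

**Structure.** One parent and one offspring per family; parents sampled at
pregnancy (mothers only) and midlife (mean age 50.2 ± 5.4, pregnancy 21.1
years earlier), offspring at birth, childhood (7.4 ± 0.1) and adolescence
(17.4 ± 0.9). Defaults (1049 families, 518/1049 mothers, offspring
availability 438/601/626 out of 1049) mirror a realistic two-generation
epigenetic cohort's sample flow. Covariates: age, sex, BMI, a smoking
indicator, and six leukocyte proportions drawn from a Dirichlet with
blood-typical means (gran 0.55, cd4t 0.17, cd8t 0.10, mono 0.08, bcell
0.06, nk 0.04).

**Intake.** A zero-inflated log-normal expressed as a monotone transform
of a standard normal latent: the lowest `p_nondrinker` (default 0.05)
quantiles map to exactly zero, the rest to the matching log-normal
quantile with overall mean 8.2 g/day and sdlog 0.8. This parameterization
(rather than four free category fractions) keeps the distribution and the
implied non/light/at-risk/heavy mixture — about 5/80/12/3% for women,
5/92/2/1% for men, `implied_drinker_mixture()` — internally consistent.
AUDIT is `round(clamp(2.86 + 2.8 * log(long-run intake + 1) + N(0, 3)))`
capped at 40, with self-reported non-drinkers floored at exactly 0; the
constants were chosen from the closed-form moments to give a midlife mean
near 8.1 and ~2.3% of scores above 15, typical of population cohorts at
midlife.

**Methylation.** Simulated on the logit scale and inverse-logit
transformed, so raw beta values are strictly inside (0, 1) by
construction (no boundary clipping needed): baseline logit (beta-scale
baselines uniform on [0.3, 0.7]) + alcohol signal + covariate effects
(N(0, 0.05) logit units per covariate SD) + N(0, 0.3) noise. The alcohol
signal at score CpGs is $\kappa\, d_t\, \mathrm{sign}(\beta_j)\, z_i$,
where the driver $z$ and amplitude multiplier $d_t$ depend on the effect
mode: concurrent ($z = u_i(t)$, only at outcome collections),
cumulative ($z = P_i$, $d(T) = T/(T+\tau)$ with $\tau$ = 10 years and
drinking onset at 15), genetic-stable ($z = g_i$ at every collection
including birth), smoking-confounded (concurrent plus a smoking effect
aligned with the score, smoking correlated 0.5 with drinking), or null.
Exposure modes deliberately place no signal at pregnancy, birth or
childhood: those are the design's no/low-exposure collections (pregnancy
abstinence plus within-gestation decay is the default assumption; the
true temporal decay of alcohol-related methylation is unknown, and the
duration half-life parameter makes no claim about its real value).

**Calibration.** Effect sizes are specified as the target score–outcome R²
of the largest set against log intake at the reference collection and
solved internally for $\kappa$. With $z$ and the logit noise jointly
Gaussian, Stein's lemma gives each CpG's beta-scale slope as
$\kappa d\, E[\sigma'(\ell_j)]$ and Gauss–Hermite quadrature (48 nodes)
the moments of $\sigma(\ell_j)$; the outcome moments (variance of
$h(u) = \log(\text{intake}(u)+1)$ and its covariance with the latent) come
from adaptive quadrature over the smooth positive branch. The resulting
$R^2(\kappa)$ is solved by `uniroot`; infeasible targets fail fast with
the feasible bound. In genetic mode the score's stable-variance share
(default 0.85, which also fixes the cross-time score correlation) is
solved first and the drinking heritability derived from the target. The
closed-form true R² per coefficient set is stored with every cohort; at
n = 1049 the empirical mean recovered adjusted R² matches the target to
about ±0.001 with per-seed SD ~0.017 — the sampling floor
$2\rho(1-\rho^2)/\sqrt{n}$, which is why per-seed checks are stated at
their nominal coverage rather than as absolute bounds.

**What the generator does not emulate.** Probe-level array artifacts
(batch, dye bias, detection failures), genotype structure at base-pair
resolution ($g_i$ is an abstract stable component), parent–offspring
genetic correlation, and reporting noise in self-reported intake. The
last one matters for interpretation: simulated intake is a deterministic
transform of the drinking latent, so simulated intake R² is at least the
AUDIT R², whereas real cohorts tend to show the reverse (AUDIT being the
more stable measure). Passing tests therefore demonstrate the pipeline's
correctness and the design's discriminating power under these idealized
conditions, not the biomarker's field performance.

## Problem sizes used by the tests

The module suites run on small fixtures (tens to hundreds of samples).
The end-to-end suite uses the sizes the analyses are designed around:
scoring oracle equivalence on 100 random 200 × 144 fixtures; AUC oracle
equivalence on 1000 instances (n ≤ 50, with ties); overfitting on 200
pure-noise cohorts of n = 500; effect recovery on 200 cohorts of n = 1049;
type-I error of the early-score test on 2000 mothers-only paired cohorts
of n = 518 with power assessed on 300 genetic-mode cohorts; and the
exposure-duration contrast on 200 paired generations. The analysis
scripts under `analysis/` use reduced replicate counts for quick
interactive runs and say so inline.

## Known limitations

- The coefficient family shipped is synthetic; conclusions about the real
  published biomarker require supplying its weights.
- AUDIT is generated as a noisy monotone function of a single long-run
  intake summary; real AUDIT has ten items with dependence structure.
- Pregnancy/midlife pairing assumes one parent per family and treats the
  518 mothers as a simple subset; fathers contribute to midlife totals
  but have no earlier collection.
- The smoking-confounded mode injects confounding aligned with the score
  direction at every score CpG — a worst-case geometry chosen to make the
  sensitivity rerun's direction unambiguous.
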