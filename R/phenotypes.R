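#' Drinking-frequency category to occasions-per-week midpoints
#'
#' Questionnaire frequency categories are mapped to drinking occasions per
#' week via fixed midpoints. The mapping is a declared convention of this
#' package (questionnaire-derived cohorts rarely publish theirs) and can be
#' overridden by passing a modified copy to [derive_intake()].
#'
#' @return Named numeric vector: occasions/week per canonical category token.
#' @export
frequency_midpoints <- function() {
  c(never            = 0,
    monthly_or_less  = 0.25,
    "2_4_per_month"  = 0.75,
    "2_4_per_week"   = 3,
    "4_plus_per_week" = 5)
}

# Printed questionnaire labels accepted as synonyms for the canonical tokens.
.freq_synonyms <- c(
  "Never"                 = "never",
  "Monthly or less"       = "monthly_or_less",
  "2 to 4 times a month"  = "2_4_per_month",
  "2 to 4 times a week"   = "2_4_per_week",
  "4 or more times a week" = "4_plus_per_week"
)

#' Derive alcohol intake in grammes of ethanol per day
#'
#' Intake is drinking frequency times typical quantity, converted from UK
#' units/week to grammes/day using 8 g ethanol per UK unit:
#' \deqn{\mathrm{intake} = \mathrm{occasions/week} \times \mathrm{units/occasion} \times 8 / 7.}
#' Frequency may be a questionnaire category (see [frequency_midpoints()])
#' or a non-negative numeric occasions-per-week. `"never"` yields 0
#' regardless of the reported quantity.
#'
#' @param frequency Character category vector or non-negative numeric
#'   occasions/week.
#' @param quantity Typical UK units per occasion (non-negative numeric).
#' @param midpoints Category-to-occasions/week map, default
#'   [frequency_midpoints()].
#' @return Numeric vector of grammes ethanol/day.
#' @export
derive_intake <- function(frequency, quantity, midpoints = frequency_midpoints()) {
  if (any(!is.finite(quantity) | quantity < 0)) {
    stop("quantity must be non-negative and finite")
  }
  if (is.numeric(frequency)) {
    if (any(!is.finite(frequency) | frequency < 0)) {
      stop("numeric frequency must be non-negative occasions/week")
    }
    occ <- frequency
    never <- occ == 0
  } else {
    f <- as.character(frequency)
    syn <- .freq_synonyms[f]
    f <- ifelse(is.na(syn), f, syn)
    unknown <- setdiff(unique(f), names(midpoints))
    if (length(unknown)) {
      stop("unknown frequency categor", if (length(unknown) > 1) "ies: " else "y: ",
           paste(unknown, collapse = ", "))
    }
    occ <- unname(midpoints[f])
    never <- f == "never"
  }
  out <- occ * quantity * 8 / 7
  out[never] <- 0
  out
}

#' Log-transform intake as log(grammes/day + 1)
#'
#' @param intake_gday Non-negative intake in grammes ethanol/day.
#' @return Natural log of (intake + 1); 0 maps to 0.
#' @export
log_intake <- function(intake_gday) {
  if (any(!is.finite(intake_gday) | intake_gday < 0)) {
    stop("intake must be non-negative and finite")
  }
  log(intake_gday + 1)
}

#' Categorize drinkers by sex-specific intake thresholds
#'
#' Non-drinkers report exactly 0 g/day. Women: light (0, 14], at-risk
#' (14, 28), heavy >= 28 g/day. Men: light (0, 28], at-risk (28, 42),
#' heavy >= 42 g/day. The heavy thresholds take precedence at the
#' boundaries; categories are exhaustive and mutually exclusive over
#' intake >= 0.
#'
#' @param intake_gday Non-negative intake in grammes/day.
#' @param sex `"female"`/`"male"`, or numeric with 1 = female, 0 = male.
#' @return Factor with levels `non`, `light`, `at_risk`, `heavy`.
#' @export
categorize_drinker <- function(intake_gday, sex) {
  if (any(!is.finite(intake_gday) | intake_gday < 0)) {
    stop("intake must be non-negative and finite")
  }
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1) | (is.na(sex)))) {
      stop("numeric sex must be coded 0 = male, 1 = female")
    }
    female <- sex == 1
  } else {
    s <- tolower(as.character(sex))
    ok <- s %in% c("female", "male", "f", "m") | is.na(s)
    if (!all(ok)) stop("sex must be 'female'/'male' (or 0/1)")
    female <- s %in% c("female", "f")
    female[is.na(s)] <- NA
  }
  if (any(is.na(female) & intake_gday > 0)) {
    stop("sex is required to categorize drinkers with non-zero intake")
  }
  light_hi <- ifelse(female, 14, 28)
  heavy_lo <- ifelse(female, 28, 42)
  out <- rep("light", length(intake_gday))
  out[intake_gday == 0] <- "non"
  out[intake_gday > light_hi] <- "at_risk"
  out[intake_gday >= heavy_lo] <- "heavy"
  factor(out, levels = c("non", "light", "at_risk", "heavy"))
}

#' Dichotomize AUDIT score at the high-risk cut point
#'
#' AUDIT totals range 0-40; scores above 15 flag high alcohol-use-disorder
#' risk (15 itself is low).
#'
#' @param audit Integer-ish vector in \[0, 40\].
#' @return Logical vector, `TRUE` when `audit > 15`.
#' @export
dichotomize_audit <- function(audit) {
  if (any(!is.finite(audit) | audit < 0 | audit > 40)) {
    stop("AUDIT scores must lie in [0, 40]")
  }
  audit > 15
}

#' Derive the full phenotype table from raw questionnaire fields
#'
#' Convenience wrapper that augments a phenotype table holding
#' `freq_per_week` (or a `frequency` category column), `quantity_units`,
#' `audit` with derived `intake_gday`, `log_intake`, `category` and
#' `audit_high`. Sex is taken from a matching covariate table.
#'
#' @param pheno Data frame with `sample_id`, frequency/quantity, `audit`.
#' @param covars Data frame with `sample_id` and `sex`.
#' @return `pheno` with the derived columns appended.
#' @export
derive_phenotypes <- function(pheno, covars) {
  stopifnot("sample_id" %in% names(pheno), "sample_id" %in% names(covars))
  freq <- if ("freq_per_week" %in% names(pheno)) pheno$freq_per_week else pheno$frequency
  pheno$intake_gday <- derive_intake(freq, pheno$quantity_units)
  pheno$log_intake <- log_intake(pheno$intake_gday)
  sex <- covars$sex[match(pheno$sample_id, covars$sample_id)]
  pheno$category <- categorize_drinker(pheno$intake_gday, sex)
  pheno$audit_high <- dichotomize_audit(pheno$audit)
  pheno
}
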