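Package: methalc
Title: Validation of Weighted DNA Methylation Alcohol Biomarker Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate weighted CpG methylation alcohol biomarker
    scores (DNAm-Alc) across the life course. Computes nested weighted-sum
    scores from beta-value matrices, residualizes methylation on
    time-point-specific covariate sets by ordinary least squares, derives
    alcohol intake (grammes ethanol/day) and drinker categories from
    frequency-by-quantity questionnaire items, evaluates scores against
    intake and AUDIT by adjusted R-squared and Mann-Whitney ROC/AUC,
    contrasts fixed-coefficient scores with in-sample coefficient refits to
    quantify overfitting, and runs the earlier-versus-concurrent
    longitudinal regression design that tests for genetic or stable
    environmental confounding. A synthetic two-generation longitudinal
    cohort generator with closed-form effect-size calibration provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
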