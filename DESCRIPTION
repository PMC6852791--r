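Package: diabtmle
Title: Targeted Learning Evaluation of a Multidisciplinary Diabetes Care
    Program
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-analysis pipeline for evaluating the effect of a
    multidisciplinary diabetes care program (DIABETIMSS) on glycemic control
    using serial cross-sectional electronic health records.  Provides data
    cleaning with plausibility filters, outcome construction from HbA1c and
    fasting-glucose series, a seeded multi-clinic synthetic data generator
    with known ground-truth treatment effects and missing-at-random outcome
    missingness, a V-fold cross-validated Super Learner ensemble, three
    average-treatment-effect estimators (unadjusted, logistic g-computation,
    and targeted maximum likelihood estimation with influence-curve
    inference), blip-function regression trees for treatment-effect
    heterogeneity, counterfactual prediction in conventional-care clinics,
    covariate and propensity-score diagnostics, and an estimator-comparison
    simulation study.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    class
Config/testthat/edition: 3
RoxygenNote: 7.3.3
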