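Package: cardiosens
Title: Sensitivity and Resilience to Lifestyle Exposures via Quantile
    Regression Forest Prediction Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies individuals as sensitive, resilient or neutral to
    lifestyle risk factors by contrasting observed cardiometabolic
    biomarkers (blood pressure, lipids, glycaemic traits, BMI) against
    90% conditional prediction intervals from quantile regression
    forests, estimates the excess hazard of cardiovascular disease,
    type 2 diabetes and mortality in each class with Cox proportional
    hazards models, and pools estimates across cohorts with
    DerSimonian-Laird random-effects meta-analysis. Includes a
    synthetic-cohort generator with planted latent sensitivity classes,
    trait preprocessing (medication correction, Friedewald LDL-C,
    rank-based inverse normal transformation, residual-method energy
    adjustment, implausible-reporter exclusion), correlation and
    variance-inflation predictor filtering, iterative random-forest
    imputation of mixed-type exposures, and incremental-value assessment
    of the sensitivity flag over a baseline risk score by ROC AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ranger,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
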