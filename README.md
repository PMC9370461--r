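# cardiosens

Classifying individual **sensitivity and resilience to lifestyle
exposures** from cardiometabolic biomarkers, and estimating the excess
disease hazard those classes carry.

Some people respond to an adverse lifestyle with elevated blood pressure,
lipids or glucose; others with the same exposures do not. `cardiosens`
implements a precision-prevention pipeline that makes this operational for
epidemiological cohorts:

1. **Quantile regression forests** (from-scratch C++ implementation)
   estimate, per subject, the conditional 90% prediction interval
   *I(x) = [q₀.₀₅(Y|X=x), q₀.₉₅(Y|X=x)]* of each trait *Y* (SBP, DBP,
   lipids, glucose, BMI) given lifestyle exposures *X*, via Meinshausen
   leaf-membership weights over bagged CART trees.
2. **Classification:** observed trait above the interval in the adverse
   direction → *sensitive*; below → *resilient*; inside → *neutral*
   (mirrored for protective traits such as HDL-C). With two health
   examinations ~10 years apart, a *persistence* rule keeps only
   subjects classified the same way at both visits.
3. **Time-to-event analysis:** Cox proportional-hazards models (Efron
   ties, Schoenfeld PH diagnostics) estimate each class's hazard ratio vs
   the neutral reference for CVD/T2D/mortality outcomes, per cohort.
4. **Meta-analysis:** per-cohort log-HRs are pooled per class with
   inverse-variance weights and the DerSimonian–Laird τ² estimator;
   heterogeneity via Cochran's Q; a 1-df Q test contrasts the sensitive
   and resilient pooled estimates.
5. **Incremental value:** paired logistic models compare ROC AUC of a
   baseline risk score with and without the sensitivity flag.

Supporting machinery covers the full data-preparation path — medication
corrections (+15/+10 mm Hg BP; +0.208/+1.347/−0.060/+1.290 mmol/L
TG/TC/HDL-C/LDL-C), Friedewald LDL-C, rank-based inverse normal
transformation (Blom), residual-method energy adjustment,
implausible-reporter (FIL) exclusion, correlation (>0.80) and VIF (>10)
predictor filtering, and iterative random-forest imputation of mixed-type
exposures with OOB MSE/PFC diagnostics — plus a **synthetic cohort
generator** with planted latent sensitivity classes and survival, so the
whole pipeline is testable without access-restricted cohort data.

## Worked example

Simulate two cohorts with a planted sensitive class (8% of subjects,
trait shift 2.5 residual SDs, hazard ratio 2), analyse one with the
two-visit persistence design and one with the single-visit design, and
pool:

```r
library(cardiosens)

cohorts <- list(vhu_like  = simulate_cohort(synth_config(seed = 11)),
                mdcs_like = simulate_cohort(synth_config(seed = 12)))
res <- run_pipeline(cohorts, mode = c("persistent", "single_visit"),
                    forest_params = list(n_trees = 150, min_node_size = 5),
                    seed = 99)
pooled_table(res)
#>   trait  category    hr ci_lower ci_upper k tau2      Q   Q_p subgroup_p
#> 1   sbp sensitive 1.615    1.154     2.26 2    0 0.8684 0.351     0.0022
#> 2   sbp resilient 0.645    0.398     1.04 2    0 0.0753 0.784     0.0022

res$cohort_results$mdcs_like$cox$sbp
#> Cox fit (efron ties): n = 1850, events = 425
#>            term     hr ci_lower ci_upper        p converged
#>  labelsensitive 1.4505   0.9671    2.176 0.072117      TRUE
#>  labelresilient 0.6696   0.3852    1.164 0.155162      TRUE
#>             age 1.0206   1.0071    1.034 0.002797      TRUE
#>             sex 1.1435   0.9441    1.385 0.170177      TRUE
#>             tei 1.0000   0.9997    1.000 0.766993      TRUE
```

Reading this: subjects labelled sensitive to the exposures driving the
SBP-like trait carry a pooled hazard ratio of 1.6 (95% CI 1.15–2.26)
versus neutral subjects — an attenuated recovery of the planted HR 2
(classification noise biases towards the null) — while the resilient
class trends protective; the subgroup test separates the two classes
(p ≈ 0.002). Cochran's Q shows no cohort heterogeneity, so τ² = 0 and
random- and fixed-effects pooling coincide.

Individual stages are exposed directly: `qrf()` / `predict()` /
`prediction_interval()` / `variable_importance()` for the forests,
`classify_observation()` / `persistence_label()` for the labels,
`cox_fit()` / `schoenfeld_test()`, `dl_pool()` / `cochran_q_test()` /
`subgroup_difference_test()`, `rf_impute()`, and the preprocessing
utilities. See the vignette in `vignettes/` for the model, the generator's
assumptions, and the package's design choices.

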