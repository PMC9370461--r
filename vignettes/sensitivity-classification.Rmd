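---
title: "Classifying sensitivity and resilience to lifestyle exposures with quantile regression forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sensitivity and resilience to lifestyle exposures with quantile regression forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two people with the same diet, activity pattern, and demographic profile can
carry very different cardiometabolic risk: one responds to an adverse
lifestyle with elevated blood pressure or lipids, the other does not. This
package implements a precision-prevention analysis that makes that notion
operational. For each subject it asks: *given everything we know about your
lifestyle exposures, where should your biomarker be?* A subject whose
observed trait (SBP, DBP, total cholesterol, triglycerides, HDL-C, LDL-C,
fasting or 2h glucose, BMI) lies **above** the 90% conditional prediction
interval for people with their exposure profile is called **sensitive** to
those exposures; one **below** the interval, **resilient**; everyone else,
**neutral**. (For a protective trait such as HDL-C the adverse direction is
low, and the mapping is mirrored.) The classes are then carried into a
time-to-event analysis: do the "sensitive" have excess hazard of
cardiovascular disease, type 2 diabetes, or death — beyond what the usual
risk factors explain — and does flagging them add predictive value over a
standard risk score?

Real cohort data of this kind (two health examinations a decade apart,
linked to event registries) are access-restricted, so the package ships a
synthetic-cohort generator that encodes the statistical structure the
analysis assumes, making every stage testable end to end.

## The model

### Conditional prediction intervals from quantile regression forests

For a trait $Y$ and exposures $X$, the 90% prediction interval at $x$ is

$$I(x) = [\,q_{0.05}(Y \mid X = x),\; q_{0.95}(Y \mid X = x)\,],$$

estimated with a quantile regression forest: an ensemble of CART regression
trees grown on bootstrap resamples. Each tree partitions the predictor
space; the conditional distribution at $x$ is estimated by weighting
training observation $i$ with

$$w_i(x) = \frac{1}{B}\sum_{t=1}^{B}
  \frac{k_{i,t}}{\sum_j k_{j,t}\,\mathbf 1\{x_j \in \ell_t(x)\}}
  \mathbf 1\{x_i \in \ell_t(x)\},$$

where $\ell_t(x)$ is the leaf of tree $t$ containing $x$ and $k_{i,t}$ the
bootstrap multiplicity of observation $i$ in tree $t$. The conditional CDF
estimate is $\hat F(y\mid x) = \sum_i w_i(x)\,\mathbf 1\{y_i \le y\}$ and
quantiles are its inf-type inverse — always an observed training response,
with no interpolation. Model covariates (age, centred-age squared, sex,
questionnaire version, fasting status, scheduled follow-up time) enter as
ordinary predictors alongside the exposures.

Forest defaults are `n_trees = 500`, `mtry = ceiling(p/3)`,
`min_node_size = 5`. Two implementation choices matter enough to spell out:

* **`min_node_size` is a minimum *leaf* size.** A split is admissible only
  if both children retain at least `min_node_size` bootstrap observations,
  so leaves hold between `min_node_size` and `2*min_node_size - 1`
  observations. Allowing arbitrarily small children (the other common
  reading) produces singleton leaves that hand an entire tree's vote to one
  extreme response; in our measurements that inflated interval widths and
  conditional-median error severalfold. With leaf-size semantics the
  held-out coverage of the 90% interval on a homoscedastic cohort sits
  within a point of nominal (the acceptance suite recomputes this).
* **Deterministic tie-breaking.** The split search maximizes the
  between-child sum-of-squares gain; ties go to the lowest feature index,
  then the lowest split point, and candidate features are scanned in index
  order. Together with routing all randomness through R's RNG this makes
  fits bit-reproducible under a fixed seed.

Variable importance follows regression-forest convention: %IncMSE is the
relative increase in a tree's out-of-bag MSE after permuting one feature
among that tree's out-of-bag rows, averaged over trees; IncNodePurity is
the accumulated split gain per feature. The two-sided interval at
`alpha = 0.10` is the fifth and 95th conditional quantiles.

### Classification and persistence

`classify_observation()` maps observed values against their intervals;
boundary values count as inside (the interval is closed; exact ties are
measure-zero events in continuous traits). With two examinations roughly
ten years apart, `persistence_label()` defaults to the strict rule — a
subject is persistently sensitive only when classified sensitive at *both*
visits; discordant pairs are neutral — with an `"either"` rule available.
The generator fixes the latent class at the subject level, i.e. sensitivity
is assumed stable over the inter-visit interval. That assumption is what
makes persistence recoverable at all; if sensitivity drifted, the strict
rule would mechanically shrink the persistent groups further.

### Survival and pooling

Per trait, a Cox proportional-hazards model with the neutral class as
reference estimates the hazard ratio of the sensitive and resilient
classes, adjusted for covariates (age, sex, TEI by default; the model never
re-includes a covariate already inside the trait's forest). Ties use the
Efron approximation. A label level with no events produces a monotone
likelihood; the affected estimate is reported as non-converged rather than
as a runaway number — matching the inestimable cells real small categories
produce. Proportional hazards are checked with scaled Schoenfeld residuals
against identity time (rank time switchable).

Per-cohort log hazard ratios are pooled per sensitivity category with
inverse-variance weights and the DerSimonian–Laird moment estimator of the
between-study variance $\tau^2$; heterogeneity is summarized by Cochran's
$Q$, and the sensitive-vs-resilient contrast by a 1-df $Q$ test on the two
pooled estimates. CIs are normal-approximation (no Knapp–Hartung), matching
the cited pooling method. When $Q \le k-1$, $\tau^2 = 0$ and random- and
fixed-effects pooling coincide exactly.

### Incremental predictive value

`compare_with_sensitivity()` fits two logistic models for an event within a
fixed horizon (10 years by default, excluding subjects censored earlier
without an event): baseline risk score alone, and baseline plus a
sensitivity flag (any-trait by default). Discrimination is compared by ROC
AUC, computed as the tie-corrected Mann–Whitney probability. The published
risk-score coefficient sets are external documents, so the baseline score
is pluggable; the shipped `base_risk_score()` is a synthetic logistic score
in age, sex and either SBP + total cholesterol or BMI.

## What the synthetic cohorts emulate

`synth_config()` defaults encode the study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 4000 | desk-scale cohort with enough events per class |
| `n_exposures`, `block_size` | 30, 5 | correlated lifestyle blocks (diet/activity clusters) |
| `block_correlation` | 0.35 | moderate within-block correlation; raises to >0.8 only in filter tests |
| `dichotomize_frac` | 0.2 | trailing columns thresholded into dummies, as categorical items are |
| `effects` | 0.3 on 10 of 30 exposures | trait signal-to-noise (R² ≈ 0.68) typical of well-predicted traits |
| `noise_sd` | 1 | residual trait scale; shifts are expressed in this unit |
| `prop_sensitive`, `prop_resilient` | 0.08 each | latent classes small but estimable |
| `shift_multiplier` | 2.5 | adverse shift of 2.5 residual SDs, beyond the 1.645-SD interval bound |
| `hazard_log_hr` | log 2 | planted excess hazard of the sensitive class |
| `baseline_hazard` | 0.015/yr | ≈20% cumulative events over follow-up in the neutral class |
| `censor_horizon` | 20 y | administrative exit uniform over the horizon's upper half (staggered entry) |
| `visit_gap`, `ar_coef` | 10 y, 0.8 | visits a decade apart with realistically correlated exposures |

Traits are linear in the exposures plus Gaussian noise; survival is
exponential with the class log-HR and small age/sex effects. One generator
subtlety is deliberate: the `followup_time` covariate carried into the
forests is the *scheduled administrative* follow-up (known at baseline),
not the realized time-to-event. Using realized follow-up as a trait
predictor lets the forest partially explain the class shift through early
events and anti-selects exactly the sensitive subjects who go on to have
events — a leakage worth knowing about when assembling real analysis
datasets too.

What the generator does **not** emulate: real marginal distributions of
food-frequency items, measurement-instrument changes between eras,
ICD-coded competing outcomes, non-random missingness, or time-varying
sensitivity. Passing tests therefore show the machinery is correct and
calibrated under the stated assumptions, not that real cohorts satisfy
those assumptions.

## Numerical and design choices

* **Inverse normal transform:** Blom offset, `qnorm((r - 3/8)/(n + 1/4))`,
  averaged ranks for ties; the common epidemiological default.
* **Friedewald LDL-C:** `tc - hdl - tg/2.2` (mmol/L), invalid at
  TG ≥ 4.52 mmol/L (400 mg/dL), returned as missing-with-reason.
* **Correlation filter:** greedy; the member of the worst pair with the
  larger mean absolute correlation is dropped; deterministic order.
* **VIF filter:** iterative largest-first removal; exact collinearity is
  treated as infinite VIF, ties resolved by mean absolute correlation.
* **Imputation:** missForest-style iterative forests (100 trees/column),
  increasing-missingness column order, mixed-type stopping rule (stop at
  the first increase of the continuous and categorical change criteria,
  return the previous iterate). Columns at ≥50% missingness are excluded
  from imputation; only exposures, never traits, are imputed.
* **Pipeline order:** energy adjustment → inverse-normal transform →
  correlation filter → imputation → split → VIF filter → forest. The
  train/test split is subject-level so both visits stay on one side.
* **age²** is built from centred age, avoiding the near-collinearity of
  raw age and age² that would otherwise have the VIF filter remove one.

## Known limitations

* **Persistence attenuates power.** The strict both-visit rule at
  `n_subjects = 4000` yields persistent sensitive groups of a few dozen
  subjects; their hazard estimates are noisy and, pooled under random
  effects, reach significance in a markedly smaller fraction of replicate
  runs than single-visit labels do (the acceptance suite's recovery check
  therefore runs the single-visit design; the mixed design is exercised
  in unit tests). At real-cohort scale this is the same trade-off,
  softened by sample size.
* **Classification noise biases hazard ratios towards the null**; the
  test suite checks this attenuation property explicitly. Pooled pipeline
  estimates should be read as lower bounds on the latent-class effect.
* Conditional quantiles are pointwise noisy where training responses are
  extreme and isolated, especially with few predictors; interval coverage
  is calibrated on average, not at every $x$.
* The DL estimator with two cohorts estimates $\tau^2$ from one degree of
  freedom; heterogeneity inflates pooled CIs sharply.

## Problem sizes used by the test and acceptance suites

Interval calibration runs at `n_train = n_test = 5000`, `p = 10`, default
forest; end-to-end recovery at two cohorts of 4000 subjects with 150-tree
forests over 20 seeds; global-null calibration at the same cohort size with
50-tree forests. These sizes were chosen to keep replicate counts high at
desk scale while leaving the generator's study conditions untouched.
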