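#' Maximum-likelihood logistic regression
#'
#' Thin wrapper over [stats::glm()] (binomial family, IRLS run to a tight
#' tolerance) returning the coefficient table and the linear predictor.
#' Quasi- or complete separation is flagged as non-converged rather than
#' reported as a huge finite estimate.
#'
#' @param outcome 0/1 vector.
#' @param predictors data frame or matrix of predictors (may be empty for
#'   an intercept-only model).
#' @return list of class `"logistic_fit"`: `coefficients` (data frame with
#'   `term`, `estimate`, `se`, `ci_lower`, `ci_upper`, `p`), `linear_pred`,
#'   `fitted`, `converged`, `separated`.
#' @export
fit_logistic <- function(outcome, predictors = NULL) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2) {
    stop("both outcome classes must be present")
  }
  df <- if (is.null(predictors) || NCOL(predictors) == 0) {
    data.frame(.y = outcome)
  } else {
    cbind(data.frame(.y = outcome), as.data.frame(predictors))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10,
                                            maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   p = sm[, 4], row.names = NULL)
  co$ci_lower <- co$estimate - 1.96 * co$se
  co$ci_upper <- co$estimate + 1.96 * co$se
  if (separated) co[, c("estimate", "se", "ci_lower", "ci_upper", "p")] <-
    co[, c("estimate", "se", "ci_lower", "ci_upper", "p")] * NA
  structure(list(coefficients = co,
                 linear_pred = as.numeric(fit$linear.predictors),
                 fitted = as.numeric(fit$fitted.values),
                 converged = fit$converged && !separated,
                 separated = separated,
                 glm = fit),
            class = "logistic_fit")
}

#' ROC area under the curve
#'
#' The Mann-Whitney probability that a random event subject scores higher
#' than a random non-event subject, with ties counting one half (so a
#' constant score gives exactly 0.5). Invariant under strictly monotone
#' transforms of the score, and `roc_auc(-s, y) = 1 - roc_auc(s, y)`.
#'
#' @param scores numeric risk scores.
#' @param outcomes 0/1 outcomes, same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, outcomes) {
  ok <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[ok]
  outcomes <- as.integer(outcomes[ok])
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Synthetic baseline cardiovascular risk score
#'
#' A pluggable stand-in for a published risk algorithm: the linear
#' predictor of a logistic model in age, sex and either systolic blood
#' pressure plus total cholesterol (laboratory version) or BMI
#' (non-laboratory version). Any user-supplied score vector can be used in
#' its place throughout [compare_with_sensitivity()].
#'
#' @param data data frame with columns `age`, `sex` and `sbp` + `tc`
#'   (laboratory) or `bmi` (non-laboratory); traits may be on any
#'   consistent scale, they are standardized internally.
#' @param type `"laboratory"` or `"nonlaboratory"`.
#' @return numeric score vector (higher = riskier).
#' @export
base_risk_score <- function(data, type = c("laboratory", "nonlaboratory")) {
  type <- match.arg(type)
  z <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  s <- 0.06 * (data$age - 50) + 0.4 * data$sex
  if (type == "laboratory") {
    s + 0.5 * z(data$sbp) + 0.3 * z(data$tc)
  } else {
    s + 0.4 * z(data$bmi)
  }
}

#' Incremental predictive value of the sensitivity flag
#'
#' Fits two logistic models for the binary outcome — baseline risk score
#' alone, and baseline score plus the sensitivity indicator — and compares
#' their in-sample ROC AUCs.
#'
#' @param base_score numeric baseline risk score.
#' @param sensitivity sensitivity indicator: 0/1, logical, or a label
#'   factor (coerced to `label == "sensitive"`).
#' @param outcomes 0/1 outcome vector.
#' @return object of class `"auc_comparison"`: list with `auc_base`,
#'   `auc_with_sensitivity`, `delta_auc`, `n`, `n_events` and both fits.
#' @export
compare_with_sensitivity <- function(base_score, sensitivity, outcomes) {
  if (is.factor(sensitivity) || is.character(sensitivity)) {
    sensitivity <- as.integer(as.character(sensitivity) == "sensitive")
  }
  sensitivity <- as.numeric(sensitivity)
  ok <- !is.na(base_score) & !is.na(sensitivity) & !is.na(outcomes)
  base_score <- base_score[ok]
  sensitivity <- sensitivity[ok]
  outcomes <- as.integer(outcomes[ok])
  fit0 <- fit_logistic(outcomes, data.frame(score = base_score))
  fit1 <- fit_logistic(outcomes, data.frame(score = base_score,
                                            sensitive = sensitivity))
  auc0 <- roc_auc(fit0$linear_pred, outcomes)
  auc1 <- roc_auc(fit1$linear_pred, outcomes)
  structure(list(auc_base = auc0, auc_with_sensitivity = auc1,
                 delta_auc = auc1 - auc0, n = length(outcomes),
                 n_events = sum(outcomes), fit_base = fit0,
                 fit_with_sensitivity = fit1),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "ROC AUC: base %.4f, base + sensitivity %.4f (delta %+.4f); %d/%d events\n",
    x$auc_base, x$auc_with_sensitivity, x$delta_auc, x$n_events, x$n))
  invisible(x)
}
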