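#' Cox proportional hazards fit for sensitivity classes
#'
#' Estimates hazard ratios of the sensitive and resilient classes versus
#' the neutral reference, optionally adjusted for covariates, by
#' maximizing the Cox partial likelihood (Efron tie handling by default).
#' Model fitting is delegated to [survival::coxph()]; this wrapper builds
#' the design (label factor releveled to neutral), extracts per-term
#' log-HRs with standard errors from the inverse observed information,
#' Wald p-values and 95% CIs, and flags monotone-likelihood terms — e.g. a
#' class with no events — as non-converged instead of reporting a
#' runaway estimate.
#'
#' @param data data frame with columns `time`, `event`, `label` (factor
#'   with levels `neutral`, `sensitive`, `resilient`) and any covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `"cox_fit"`: list with `estimates` (data frame:
#'   `term`, `log_hr`, `se`, `hr`, `ci_lower`, `ci_upper`, `p`,
#'   `converged`), `n`, `n_events`, `events_by_label`, `loglik` and the
#'   underlying `coxph` fit.
#' @export
cox_fit <- function(data, covariates = character(0),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event", "label") %in% names(data)))
  data <- data[!is.na(data$label) & !is.na(data$time), , drop = FALSE]
  if (any(data$time <= 0)) stop("event/censoring times must be positive")
  if (sum(data$event) < 2) stop("need at least 2 events")
  data$label <- stats::relevel(factor(data$label), ref = "neutral")
  rhs <- paste(c("label", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  # monotone-likelihood warnings are handled below by flagging the term
  # as non-converged, so they are not re-surfaced to the caller
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  events_by_label <- tapply(data$event, data$label, sum)
  events_by_label[is.na(events_by_label)] <- 0
  # monotone likelihood: a label level present in the data but with no
  # events (or absent entirely) cannot be estimated; mirror a "-" cell
  no_event_levels <- names(events_by_label)[events_by_label == 0]
  runaway <- abs(beta) > 15 | se > 100
  est <- data.frame(term = names(beta), log_hr = as.numeric(beta),
                    se = as.numeric(se))
  est$converged <- !runaway
  for (lv in no_event_levels) {
    est$converged[est$term == paste0("label", lv)] <- FALSE
  }
  est[!est$converged, c("log_hr", "se")] <- NA_real_
  est$hr <- exp(est$log_hr)
  est$ci_lower <- exp(est$log_hr - 1.96 * est$se)
  est$ci_upper <- exp(est$log_hr + 1.96 * est$se)
  est$p <- 2 * stats::pnorm(-abs(est$log_hr / est$se))
  structure(list(
    estimates = est,
    n = nrow(data),
    n_events = sum(data$event),
    events_by_label = events_by_label,
    loglik = fit$loglik[length(fit$loglik)],
    ties = ties,
    coxph = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d\n", x$ties, x$n,
              x$n_events))
  print(x$estimates[, c("term", "hr", "ci_lower", "ci_upper", "p",
                        "converged")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Scaled Schoenfeld residuals at the event times are regressed on
#' (transformed) event time; a non-zero slope indicates a time-varying
#' effect, i.e. a proportional-hazards violation. Delegates to
#' [survival::cox.zph()] with the identity time transform by default
#' (switchable to rank time).
#'
#' @param fit a [cox_fit()] object (must have converged overall).
#' @param transform `"identity"` (default) or `"rank"`.
#' @return data frame with one row per term plus a `GLOBAL` row, columns
#'   `term`, `chisq`, `df`, `p`.
#' @export
schoenfeld_test <- function(fit, transform = c("identity", "rank")) {
  transform <- match.arg(transform)
  if (fit$n_events < 2) stop("need at least 2 events")
  zph <- survival::cox.zph(fit$coxph, transform = transform)
  tab <- as.data.frame(zph$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL)
}

#' Extract a per-cohort study estimate from a Cox fit
#'
#' Pulls one term's log-HR and SE out of a [cox_fit()] for downstream
#' pooling. Non-converged terms yield `NULL` (the cohort contributes no
#' estimate for that category, as when no events occurred in a class).
#'
#' @param fit a [cox_fit()].
#' @param category `"sensitive"` or `"resilient"`.
#' @param cohort cohort label.
#' @param trait,outcome carried through for bookkeeping.
#' @return a [study_estimate()] or `NULL`.
#' @export
cox_study_estimate <- function(fit, category, cohort = "cohort",
                               trait = NA_character_,
                               outcome = NA_character_) {
  row <- fit$estimates[fit$estimates$term == paste0("label", category), ,
                       drop = FALSE]
  if (nrow(row) == 0 || !isTRUE(row$converged)) return(NULL)
  study_estimate(cohort = cohort, log_hr = row$log_hr, se = row$se,
                 category = category, trait = trait, outcome = outcome)
}
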