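#' A per-cohort hazard estimate for pooling
#'
#' @param cohort cohort label.
#' @param log_hr log hazard ratio.
#' @param se its standard error (positive).
#' @param category `"sensitive"` or `"resilient"`.
#' @param trait,outcome bookkeeping labels.
#' @return list of class `"study_estimate"`.
#' @export
study_estimate <- function(cohort, log_hr, se, category = NA_character_,
                           trait = NA_character_, outcome = NA_character_) {
  if (!is.finite(log_hr) || !is.finite(se) || se <= 0) {
    stop("log_hr must be finite and se positive")
  }
  structure(list(cohort = cohort, log_hr = log_hr, se = se,
                 category = category, trait = trait, outcome = outcome),
            class = "study_estimate")
}

est_matrix <- function(estimates) {
  if (inherits(estimates, "study_estimate")) estimates <- list(estimates)
  k <- length(estimates)
  if (k == 0) stop("no study estimates supplied")
  theta <- vapply(estimates, function(e) e$log_hr, numeric(1))
  se <- vapply(estimates, function(e) e$se, numeric(1))
  list(theta = theta, se = se, k = k)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Inverse-variance pooling of per-cohort log hazard ratios. Fixed-effect
#' weights are `w_i = 1/SE_i^2`; heterogeneity is
#' `Q = sum w_i (theta_i - theta_fixed)^2`, and the between-study variance
#' is the DerSimonian-Laird moment estimator
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`. Random-effect
#' weights `1/(SE_i^2 + tau^2)` give the pooled estimate and its normal
#' 95% CI on the hazard-ratio scale. With a single study the pooled result
#' equals the study and `Q = tau^2 = 0`; when `Q <= k - 1`, `tau^2 = 0`
#' and random- and fixed-effects pooling coincide.
#'
#' @param estimates list of [study_estimate()]s (or a single one).
#' @param method `"random"` (default) or `"fixed"`.
#' @return object of class `"meta_result"`: list with `log_hr`, `se`,
#'   `hr`, `ci_lower`, `ci_upper`, `p`, `tau2`, `Q`, `Q_df`, `Q_p`, `k`
#'   and `method`.
#' @export
dl_pool <- function(estimates, method = c("random", "fixed")) {
  method <- match.arg(method)
  m <- est_matrix(estimates)
  w <- 1 / m$se^2
  theta_fixed <- sum(w * m$theta) / sum(w)
  Q <- sum(w * (m$theta - theta_fixed)^2)
  df <- m$k - 1L
  tau2 <- if (df > 0) {
    max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  } else 0
  if (method == "random") {
    wr <- 1 / (m$se^2 + tau2)
    pooled <- sum(wr * m$theta) / sum(wr)
    se <- sqrt(1 / sum(wr))
  } else {
    pooled <- theta_fixed
    se <- sqrt(1 / sum(w))
  }
  structure(list(
    log_hr = pooled, se = se, hr = exp(pooled),
    ci_lower = exp(pooled - 1.96 * se),
    ci_upper = exp(pooled + 1.96 * se),
    p = 2 * stats::pnorm(-abs(pooled / se)),
    tau2 = tau2, Q = Q, Q_df = df,
    Q_p = if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
    k = m$k, method = method
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Pooled (%s effects, k = %d): HR %.3f [%.3f, %.3f], p = %.3g\n",
    x$method, x$k, x$hr, x$ci_lower, x$ci_upper, x$p))
  cat(sprintf("  tau2 = %.4g, Q = %.3f (df %d, p = %.3g)\n", x$tau2, x$Q,
              x$Q_df, if (is.na(x$Q_p)) NA else x$Q_p))
  invisible(x)
}

#' Cochran's Q heterogeneity test
#'
#' @param estimates list of at least two [study_estimate()]s.
#' @return list with `Q`, `df` and chi-square `p`.
#' @export
cochran_q_test <- function(estimates) {
  m <- est_matrix(estimates)
  if (m$k < 2) stop("need at least 2 studies")
  w <- 1 / m$se^2
  theta_fixed <- sum(w * m$theta) / sum(w)
  Q <- sum(w * (m$theta - theta_fixed)^2)
  df <- m$k - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Test for subgroup differences between pooled categories
#'
#' Compares the pooled resilient and pooled sensitive estimates with
#' `z = (theta_r - theta_s) / sqrt(SE_r^2 + SE_s^2)`, reported as
#' `Q = z^2` against chi-square with 1 df (symmetric in the two groups).
#' Either pooled result missing (`NULL`) gives an undefined (`NA`) result,
#' as when a category had too few events to pool.
#'
#' @param pooled_resilient,pooled_sensitive [dl_pool()] results or `NULL`.
#' @return list with `Q`, `df = 1` and `p` (all `NA` if undefined).
#' @export
subgroup_difference_test <- function(pooled_resilient, pooled_sensitive) {
  if (is.null(pooled_resilient) || is.null(pooled_sensitive)) {
    return(list(Q = NA_real_, df = 1L, p = NA_real_))
  }
  z <- (pooled_resilient$log_hr - pooled_sensitive$log_hr) /
    sqrt(pooled_resilient$se^2 + pooled_sensitive$se^2)
  list(Q = z^2, df = 1L, p = stats::pchisq(z^2, 1, lower.tail = FALSE))
}
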