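mk_surv_cohort <- function(seed, n = 2000, log_hr = log(2),
                           p_sens = 0.15, p_res = 0.1) {
  cfg <- synth_config(n_subjects = n, n_exposures = 2, block_size = 1,
                      effects = list(t = rep(0, 2)), dichotomize_frac = 0,
                      prop_sensitive = p_sens, prop_resilient = p_res,
                      hazard_log_hr = log_hr, seed = seed)
  cls <- assign_latent_class(cfg)
  sv <- generate_survival(cls, covariates = NULL, cfg = cfg)
  data.frame(time = sv$time, event = sv$event, label = cls)
}

test_that("a permuted label carries no hazard signal", {
  set.seed(101)
  d <- mk_surv_cohort(101, n = 1500)
  d$label <- sample(d$label)
  fit <- cox_fit(d)
  sens <- fit$estimates[fit$estimates$term == "labelsensitive", ]
  expect_lt(abs(sens$log_hr), 3 * sens$se)
  expect_true(sens$ci_lower <= 1 && sens$ci_upper >= 1)
})

test_that("the fitted log-HR maximizes the hand-written partial likelihood", {
  # tie-free 6-subject toy, one binary group
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                  event = c(1, 1, 1, 0, 1, 0),
                  label = factor(c("sensitive", "sensitive", "neutral",
                                   "neutral", "sensitive", "neutral"),
                                 levels = c("neutral", "sensitive",
                                            "resilient")))
  fit <- cox_fit(d)
  beta_hat <- fit$estimates$log_hr[fit$estimates$term == "labelsensitive"]
  x <- as.integer(d$label == "sensitive")
  # independent oracle: coarse grid on the hand-written partial likelihood,
  # refined by golden-section search
  grid <- seq(-4, 4, by = 0.01)
  nll <- vapply(grid, neg_log_partial_lik, numeric(1),
                time = d$time, event = d$event, x = x)
  b0 <- grid[which.min(nll)]
  opt <- optimize(neg_log_partial_lik, c(b0 - 0.02, b0 + 0.02),
                  time = d$time, event = d$event, x = x, tol = 1e-9)
  expect_equal(beta_hat, opt$minimum, tolerance = 1e-4)
})

test_that("a planted log-2 hazard is recovered with nominal CI coverage", {
  hits <- 0L
  for (s in 1:20) {
    d <- mk_surv_cohort(200 + s, n = 4000)
    fit <- cox_fit(d)
    sens <- fit$estimates[fit$estimates$term == "labelsensitive", ]
    hits <- hits + (sens$ci_lower <= 2 && sens$ci_upper >= 2)
  }
  expect_gte(hits, 18L)   # >= 90% of 20 seeds
})

test_that("estimates are invariant to the time unit", {
  d <- mk_surv_cohort(103, n = 800)
  f_years <- cox_fit(d)
  d$time <- d$time * 365.25
  f_days <- cox_fit(d)
  expect_equal(f_years$estimates$log_hr, f_days$estimates$log_hr,
               tolerance = 1e-10)
})

test_that("a class without events is flagged as non-converged, like an inestimable cell", {
  set.seed(104)
  d <- mk_surv_cohort(104, n = 400, p_res = 0.1)
  d$event[d$label == "resilient"] <- 0
  fit <- cox_fit(d)
  res_row <- fit$estimates[fit$estimates$term == "labelresilient", ]
  expect_false(res_row$converged)
  expect_true(is.na(res_row$hr))
  sens_row <- fit$estimates[fit$estimates$term == "labelsensitive", ]
  expect_true(sens_row$converged)
  expect_error(cox_fit(d[d$event == 0, ]), "at least 2 events")
})

test_that("Schoenfeld test keeps its size under proportional hazards", {
  ps <- vapply(105:109, function(s) {
    fit <- cox_fit(mk_surv_cohort(s, n = 2000))
    z <- schoenfeld_test(fit)
    z$p[z$term == "GLOBAL"]
  }, numeric(1))
  expect_gt(median(ps), 0.05)   # p roughly uniform under the null
  fit <- cox_fit(mk_surv_cohort(105, n = 2000))
  z <- schoenfeld_test(fit)
  # factor terms are grouped into one row (df 2) plus the global test
  expect_setequal(z$term, c("label", "GLOBAL"))
  expect_equal(z$df[z$term == "label"], 2)
})

test_that("Schoenfeld test detects a sign-flipping time-varying effect", {
  # group hazard doubled before t = 5, halved after: PH strongly violated
  set.seed(106)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  h1 <- 0.08 * exp(log(2.5) * x)   # early hazard
  h2 <- 0.08 * exp(-log(2.5) * x)  # late hazard
  t1 <- rexp(n, h1)
  t2 <- 5 + rexp(n, h2)
  time <- ifelse(t1 <= 5, t1, t2)
  event <- as.integer(time <= 20)
  time <- pmin(time, 20)
  d <- data.frame(time = time, event = event,
                  label = factor(ifelse(x == 1, "sensitive", "neutral"),
                                 levels = c("neutral", "sensitive",
                                            "resilient")))
  fit <- cox_fit(d)
  z <- schoenfeld_test(fit)
  expect_lt(z$p[z$term == "GLOBAL"], 0.01)
})
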